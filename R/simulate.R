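#' Parameters for the synthetic seed-community generator
#'
#' Defaults emulate the design of the seed microbiome survey the package
#' targets: 43 host accessions (17 wild, 26 domesticated) with 3 replicate
#' samples each, 364 bacterial and 356 fungal OTUs, log-normal abundance
#' inequality, a tunable host-phylogeny (phylosymbiosis) signal, an
#' asymmetric wild/domesticated enrichment effect, compositional multinomial
#' sampling at log-normally varying depth, and independent zero inflation.
#'
#' @param n_hosts number of host accessions.
#' @param n_wild how many hosts are wild (the rest are domesticated).
#' @param n_replicates replicate samples per host.
#' @param n_otus_bacteria,n_otus_fungi OTUs per kingdom.
#' @param depth_mean mean sequencing depth (reads/sample).
#' @param depth_dispersion log-scale sd of the per-sample depth.
#' @param lognormal_sigma sd of baseline log abundances; controls
#'   abundance inequality (Gini).
#' @param phylosym_strength `s` in `[0, 1]`: scale of the Brownian-motion
#'   host-tree component of log abundances (0 = no host-tree signal).
#' @param domestication_effect `d`: log2-scale shift applied to enriched
#'   OTUs in their favoured group.
#' @param n_enriched_wild,n_enriched_dom numbers of wild-/domesticated-
#'   enriched OTUs per kingdom.
#' @param zero_inflation_p probability in `[0, 1)` that a sampled count is
#'   masked to zero.
#' @param basis_corr_spec list of `c(i, j, rho)` ground-truth basis
#'   correlations between OTUs (combined indices; both must fall in the
#'   same kingdom block).
#' @param noise_sigma sd of the per-sample basis noise.
#' @param inherit_frac probability a maternal OTU is retained by progeny
#'   (used by [simulate_pedigree()]).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the parameters and this seed.
#' @return validated list of class `sim_params`.
#' @export
sim_params <- function(n_hosts = 43, n_wild = 17, n_replicates = 3,
                       n_otus_bacteria = 364, n_otus_fungi = 356,
                       depth_mean = 30000, depth_dispersion = 0.3,
                       lognormal_sigma = 2, phylosym_strength = 0.5,
                       domestication_effect = 3,
                       n_enriched_wild = 60, n_enriched_dom = 10,
                       zero_inflation_p = 0.3,
                       basis_corr_spec = list(), noise_sigma = 1,
                       inherit_frac = 0.8, seed = 1) {
  p <- list(n_hosts = n_hosts, n_wild = n_wild, n_replicates = n_replicates,
            n_otus_bacteria = n_otus_bacteria, n_otus_fungi = n_otus_fungi,
            depth_mean = depth_mean, depth_dispersion = depth_dispersion,
            lognormal_sigma = lognormal_sigma,
            phylosym_strength = phylosym_strength,
            domestication_effect = domestication_effect,
            n_enriched_wild = n_enriched_wild,
            n_enriched_dom = n_enriched_dom,
            zero_inflation_p = zero_inflation_p,
            basis_corr_spec = basis_corr_spec, noise_sigma = noise_sigma,
            inherit_frac = inherit_frac, seed = as.integer(seed))
  stopifnot(n_hosts >= 3, n_wild >= 1, n_wild < n_hosts, n_replicates >= 1,
            n_otus_bacteria >= 1, n_otus_fungi >= 0,
            depth_mean > 0, depth_dispersion >= 0, lognormal_sigma >= 0,
            phylosym_strength >= 0, phylosym_strength <= 1,
            zero_inflation_p >= 0, zero_inflation_p < 1,
            inherit_frac >= 0, inherit_frac <= 1, noise_sigma >= 0,
            n_enriched_wild >= 0, n_enriched_dom >= 0)
  n_tot <- n_otus_bacteria + n_otus_fungi
  for (spec in basis_corr_spec) {
    if (length(spec) != 3) stop("basis_corr_spec entries must be c(i, j, rho)")
    if (spec[1] < 1 || spec[2] < 1 || spec[1] > n_tot || spec[2] > n_tot ||
        spec[1] == spec[2])
      stop("invalid OTU indices in basis_corr_spec")
    if (abs(spec[3]) >= 1) stop("|rho| must be < 1 in basis_corr_spec")
    same_kingdom <- (spec[1] <= n_otus_bacteria) == (spec[2] <= n_otus_bacteria)
    if (!same_kingdom)
      stop("basis_corr_spec pairs must lie within one kingdom block")
  }
  structure(p, class = "sim_params")
}

#' Simulate an ultrametric host phylogeny
#'
#' A random coalescent tree: binary, ultrametric, positive branch lengths,
#' deterministic for a given seed.
#'
#' @param n_hosts number of tips (>= 3).
#' @param seed integer seed.
#' @return a `phylo` tree with tips `acc01`, `acc02`, ...
#' @export
simulate_host_tree <- function(n_hosts, seed = 1) {
  if (n_hosts < 3) stop("n_hosts must be at least 3")
  set.seed(seed)
  ape::rcoal(n_hosts, tip.label = sprintf("acc%02d", seq_len(n_hosts)))
}

# positive-definite completion of the basis correlation matrix; shrinks
# towards the identity until the smallest eigenvalue clears 1e-6
basis_sigma <- function(n, spec, offset = 0) {
  S <- diag(n)
  for (sp in spec) {
    i <- sp[1] - offset; j <- sp[2] - offset
    S[i, j] <- S[j, i] <- sp[3]
  }
  lambda <- 0
  while (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-6) {
    lambda <- lambda + 0.05
    S <- (1 - lambda) * S + lambda * diag(n)
    if (lambda >= 1) break
  }
  S
}

# latent log-abundance generator for one kingdom
simulate_kingdom <- function(params, host_tree, n_otus, prefix, spec,
                             offset, status) {
  H <- length(host_tree$tip.label)
  R <- params$n_replicates
  n_s <- H * R
  otu_ids <- sprintf("%s%03d", prefix, seq_len(n_otus))
  hosts <- host_tree$tip.label
  sample_host <- rep(hosts, each = R)
  sample_ids <- paste0(sample_host, "_r", rep(seq_len(R), H))
  mu <- stats::rnorm(n_otus, 0, params$lognormal_sigma)
  # Brownian host-tree component, unit-depth covariance
  Cs <- ape::vcv(host_tree)
  Cs <- Cs / max(diag(Cs))
  B <- t(MASS::mvrnorm(n_otus, mu = rep(0, H), Sigma = Cs))  # H x n_otus
  rownames(B) <- rownames(Cs)
  # enrichment assignment (log2 -> natural log)
  n_enr <- params$n_enriched_wild + params$n_enriched_dom
  enr_idx <- if (n_enr > 0) sample.int(n_otus, min(n_enr, n_otus)) else integer(0)
  wild_enriched <- enr_idx[seq_len(min(params$n_enriched_wild, length(enr_idx)))]
  dom_enriched <- setdiff(enr_idx, wild_enriched)
  d_ln <- params$domestication_effect * log(2)
  # correlated basis noise per sample
  S <- basis_sigma(n_otus, spec, offset)
  Lchol <- chol(S)
  E <- params$noise_sigma * t(Lchol) %*% matrix(stats::rnorm(n_otus * n_s),
                                                n_otus, n_s)
  L <- matrix(mu, n_otus, n_s) +
    params$phylosym_strength * t(B[sample_host, , drop = FALSE]) + E
  is_wild <- status[sample_host] == "wild"
  L[wild_enriched, is_wild] <- L[wild_enriched, is_wild] + d_ln
  L[dom_enriched, !is_wild] <- L[dom_enriched, !is_wild] + d_ln
  dimnames(L) <- list(otu_ids, sample_ids)
  # compositional closure + multinomial sampling at log-normal depth
  frac <- exp(sweep(L, 2, apply(L, 2, max)))
  frac <- sweep(frac, 2, colSums(frac), "/")
  depth <- round(stats::rlnorm(n_s, log(params$depth_mean) -
                                 params$depth_dispersion^2 / 2,
                               params$depth_dispersion))
  counts <- vapply(seq_len(n_s), function(j)
    stats::rmultinom(1, depth[j], frac[, j])[, 1], numeric(n_otus))
  if (params$zero_inflation_p > 0) {
    mask <- matrix(stats::runif(length(counts)) < params$zero_inflation_p,
                   n_otus, n_s)
    counts[mask] <- 0
  }
  dimnames(counts) <- list(otu_ids, sample_ids)
  list(counts = counts, latent = L, sigma = S,
       differential = data.frame(
         otu_id = otu_ids[c(wild_enriched, dom_enriched)],
         direction = rep(c("wild_enriched", "domesticated_enriched"),
                         c(length(wild_enriched), length(dom_enriched))),
         log2_fold_change = rep(c(-params$domestication_effect,
                                  params$domestication_effect),
                                c(length(wild_enriched), length(dom_enriched))),
         stringsAsFactors = FALSE))
}

#' Simulate a full synthetic seed-microbiome dataset
#'
#' Log basis abundance of each OTU in each sample is
#' `baseline + s * Brownian(host tree) + d * group indicator + correlated
#' noise`; fractions are closed to one per sample, counts drawn multinomially
#' at a log-normally distributed depth, and zeros injected by independent
#' Bernoulli masking. Bacterial and fungal tables are generated by two
#' independent draws sharing the host tree and host statuses, then merged.
#' The returned `truth` records the generating parameters, the true
#' differential OTU set, the basis correlation matrices and the latent log
#' abundances.
#'
#' @param params a [sim_params()] object.
#' @param host_tree host phylogeny; defaults to
#'   `simulate_host_tree(params$n_hosts, params$seed)`.
#' @return object of class `synthetic_dataset` with elements `counts`
#'   ([count_table()]), `host_tree`, `metadata` (data.frame), `pedigree`
#'   (a [pedigree()] over the domesticated accessions) and `truth`.
#' @export
simulate_counts <- function(params, host_tree = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(host_tree))
    host_tree <- simulate_host_tree(params$n_hosts, params$seed)
  if (length(host_tree$tip.label) < 2) stop("host tree needs >= 2 tips")
  set.seed(params$seed + 1L)
  hosts <- sort(host_tree$tip.label)
  H <- length(hosts)
  stopifnot(params$n_wild < H)
  status <- stats::setNames(rep("domesticated", H), hosts)
  status[sample(hosts, params$n_wild)] <- "wild"
  bact <- simulate_kingdom(params, host_tree, params$n_otus_bacteria, "B",
                           Filter(function(s) s[1] <= params$n_otus_bacteria,
                                  params$basis_corr_spec),
                           0, status)
  fung <- if (params$n_otus_fungi > 0)
    simulate_kingdom(params, host_tree, params$n_otus_fungi, "F",
                     Filter(function(s) s[1] > params$n_otus_bacteria,
                            params$basis_corr_spec),
                     params$n_otus_bacteria, status) else NULL
  counts <- if (is.null(fung)) bact$counts else rbind(bact$counts, fung$counts)
  kingdom <- c(rep("bacteria", params$n_otus_bacteria),
               rep("fungi", if (is.null(fung)) 0 else params$n_otus_fungi))
  names(kingdom) <- rownames(counts)
  tab <- count_table(counts, kingdom)
  # metadata: genome groups cycle over wild hosts; domesticated hosts are
  # AA and split into two breeding lines plus orphans
  ggroups <- c("AA", "BB", "CC", "CCDD", "EE", "FF", "GG", "HHJJ")
  wild_hosts <- hosts[status[hosts] == "wild"]
  dom_hosts <- hosts[status[hosts] == "domesticated"]
  genome <- stats::setNames(rep("AA", H), hosts)
  genome[wild_hosts] <- rep_len(ggroups, length(wild_hosts))
  line <- stats::setNames(rep(NA_character_, H), hosts)
  nd <- length(dom_hosts)
  n_orphan <- max(1, round(nd * 0.2))
  line[dom_hosts] <- c(rep(c("line1", "line2"),
                           length.out = nd - n_orphan),
                       rep("orphan", n_orphan))
  md <- do.call(rbind, lapply(colnames(counts), function(s) {
    h <- sub("_r[0-9]+$", "", s)
    data.frame(sample_id = s, accession = h,
               domestication_status = status[h],
               genome_group = genome[h], breeding_line = line[h],
               replicate = as.integer(sub("^.*_r", "", s)),
               stringsAsFactors = FALSE)
  }))
  rownames(md) <- NULL
  # structural pedigree over the domesticated lines: a maternal chain per line
  ped_edges <- do.call(rbind, lapply(c("line1", "line2"), function(l) {
    mem <- dom_hosts[!is.na(line[dom_hosts]) & line[dom_hosts] == l]
    if (length(mem) < 2) return(NULL)
    data.frame(child = mem[-1], mother = mem[-length(mem)], line = l,
               stringsAsFactors = FALSE)
  }))
  ped <- pedigree(ped_edges,
                  orphans = dom_hosts[!is.na(line[dom_hosts]) &
                                        line[dom_hosts] == "orphan"])
  truth <- list(params = params,
                status = status,
                differential = rbind(bact$differential,
                                     if (!is.null(fung)) fung$differential),
                basis_sigma = list(bacteria = bact$sigma,
                                   fungi = if (!is.null(fung)) fung$sigma),
                latent = rbind(bact$latent, if (!is.null(fung)) fung$latent),
                depth_model = "log-normal per-sample depth (stand-in; real library-size distributions vary by protocol)")
  structure(list(counts = tab, host_tree = host_tree, metadata = md,
                 pedigree = ped, truth = truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$counts$counts), "OTUs x",
      ncol(x$counts$counts), "samples over",
      length(x$host_tree$tip.label), "hosts\n")
  cat("  wild/domesticated:", sum(x$truth$status == "wild"), "/",
      sum(x$truth$status == "domesticated"), "\n")
  cat("  differential OTUs:", nrow(x$truth$differential), "\n")
  invisible(x)
}

#' Simulate a breeding pedigree with maternally inherited OTU sets
#'
#' Builds `n_lines` maternal breeding lines: each line has a founder, two
#' first-generation daughters (a kin pair), and a chain of descendants to
#' `depth` generations; `n_orphans` unconnected cultivars are added. Each
#' founder/orphan carries an independent Bernoulli(`base_prev`) OTU
#' presence set; each progeny retains every maternal OTU independently with
#' probability `inherit_frac` and acquires each OTU absent from its mother
#' with probability `novel_p` (so with `inherit_frac = 0` mother and
#' progeny sets are disjoint).
#'
#' @param n_lines breeding lines.
#' @param depth generations per line (>= 2).
#' @param inherit_frac maternal retention probability.
#' @param seed integer seed.
#' @param n_orphans orphan cultivars.
#' @param n_otus OTU pool size.
#' @param base_prev founder/orphan presence probability.
#' @param novel_p novel acquisition probability per absent OTU.
#' @return list with `pedigree` (a [pedigree()]), `counts` (presence/absence
#'   [count_table()], one sample per cultivar) and `truth` (per-child
#'   maternal set size and retained count, for calibration checks).
#' @export
simulate_pedigree <- function(n_lines = 2, depth = 3, inherit_frac = 0.8,
                              seed = 1, n_orphans = 3, n_otus = 400,
                              base_prev = 0.3, novel_p = 0.05) {
  if (depth < 2) stop("depth must be at least 2")
  stopifnot(inherit_frac >= 0, inherit_frac <= 1, novel_p >= 0, novel_p <= 1)
  set.seed(seed)
  edges <- NULL
  presence <- list()
  truth <- NULL
  inherit_from <- function(mother_set) {
    kept <- mother_set[stats::runif(length(mother_set)) < inherit_frac]
    novel_pool <- setdiff(seq_len(n_otus), mother_set)
    novel <- novel_pool[stats::runif(length(novel_pool)) < novel_p]
    list(set = sort(c(kept, novel)), retained = length(kept))
  }
  for (l in seq_len(n_lines)) {
    founder <- sprintf("L%d_G1", l)
    presence[[founder]] <- which(stats::runif(n_otus) < base_prev)
    sibs <- sprintf("L%d_G2%s", l, c("a", "b"))
    for (s in sibs) {
      r <- inherit_from(presence[[founder]])
      presence[[s]] <- r$set
      truth <- rbind(truth, data.frame(child = s, mother = founder,
                                       n_maternal = length(presence[[founder]]),
                                       n_retained = r$retained))
      edges <- rbind(edges, data.frame(child = s, mother = founder,
                                       line = sprintf("L%d", l)))
    }
    prev <- sibs[1]
    for (g in seq(3, depth + 1)) {
      child <- sprintf("L%d_G%d", l, g)
      r <- inherit_from(presence[[prev]])
      presence[[child]] <- r$set
      truth <- rbind(truth, data.frame(child = child, mother = prev,
                                       n_maternal = length(presence[[prev]]),
                                       n_retained = r$retained))
      edges <- rbind(edges, data.frame(child = child, mother = prev,
                                       line = sprintf("L%d", l)))
      prev <- child
    }
  }
  orphans <- if (n_orphans > 0) sprintf("orphan%d", seq_len(n_orphans)) else character(0)
  for (o in orphans) presence[[o]] <- which(stats::runif(n_otus) < base_prev)
  m <- vapply(names(presence), function(cv) {
    v <- integer(n_otus); v[presence[[cv]]] <- 1L; v
  }, integer(n_otus))
  rownames(m) <- sprintf("P%03d", seq_len(n_otus))
  kingdom <- rep(c("bacteria", "fungi"), length.out = n_otus)
  names(kingdom) <- rownames(m)
  list(pedigree = pedigree(edges, orphans = orphans),
       counts = count_table(m, kingdom),
       truth = list(inherit_frac = inherit_frac, novel_p = novel_p,
                    base_prev = base_prev, retention = truth))
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the OTU table and taxonomy TSVs, metadata TSV, newick host tree,
#' pedigree TSV, and a truth JSON (generating parameters and differential
#' OTU set).
#'
#' @param ds a [simulate_counts()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(ds$counts, file.path(dir, "otu_table.tsv"),
                    file.path(dir, "taxonomy.tsv"))
  utils::write.table(ds$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(ds$host_tree, file.path(dir, "host_tree.nwk"))
  ped <- ds$pedigree
  ped_df <- rbind(
    data.frame(child = names(ped$mother_of), mother = unname(ped$mother_of),
               line = unname(ped$line[names(ped$mother_of)])),
    if (length(ped$orphans))
      data.frame(child = ped$orphans, mother = "", line = "orphan"))
  utils::write.table(ped_df, file.path(dir, "pedigree.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- ds$truth
    jsonlite::write_json(
      list(params = truth$params[setdiff(names(truth$params), "basis_corr_spec")],
           status = as.list(truth$status),
           differential = truth$differential,
           depth_model = truth$depth_model),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
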