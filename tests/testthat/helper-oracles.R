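# Shared fixtures and independent brute-force oracles. Oracles use plain
# per-site loops over genotype counts and never call the package routines
# they are checking.

.fx <- new.env(parent = emptyenv())

# default study panel: both lineages, wheat, and the nine planted hybrids
default_sim <- function() {
  if (is.null(.fx$default)) .fx$default <- simulate_panel(sim_config())
  .fx$default
}

# complete-data panel (no missing calls, no genotype errors): the setting in
# which planted-site recoveries are exact by construction
clean_sim <- function() {
  if (is.null(.fx$clean)) {
    .fx$clean <- simulate_panel(sim_config(missing_rate = 0, seed = 7))
  }
  .fx$clean
}

# small random genotype matrix with missing data
random_gm <- function(n, m, missing = 0.1, n_chrom = 2) {
  calls <- matrix(sample(c(0L, 1L, 2L), n * m, replace = TRUE,
                         prob = c(0.45, 0.1, 0.45)), n, m)
  if (missing > 0) calls[runif(n * m) < missing] <- NA_integer_
  rownames(calls) <- sprintf("X%03d", seq_len(n))
  sites <- data.frame(id = sprintf("s%04d", seq_len(m)),
                      chrom = paste0("c", rep_len(seq_len(n_chrom), m)),
                      pos = sample.int(1e6, m), ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  genotype_matrix(calls, sites)
}

# genotype matrix from a list of per-site call vectors (sites in list order)
gm_from_cols <- function(cols, chrom = NULL) {
  m <- length(cols)
  calls <- do.call(cbind, lapply(cols, as.integer))
  rownames(calls) <- sprintf("X%03d", seq_len(nrow(calls)))
  genotype_matrix(calls, data.frame(
    id = sprintf("s%02d", seq_len(m)),
    chrom = chrom %||% rep("c1", m),
    pos = seq_len(m) * 10L, ref = "A", alt = "G", stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# allele frequency of the alt allele in a call vector; NA when no calls
.ofreq <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  sum(x) / (2 * length(x))
}

# brute-force lineage-private scan: per site, both orientations checked
oracle_private_alleles <- function(gm, part, lineages = c("L1", "L2"),
                                   min_call_fraction = 0.5) {
  ids1 <- names(part)[part == lineages[1]]
  ids2 <- names(part)[part == lineages[2]]
  out <- list()
  for (j in seq_len(n_sites(gm))) {
    x1 <- gm$calls[ids1, j]
    x2 <- gm$calls[ids2, j]
    if (mean(!is.na(x1)) < min_call_fraction) next
    if (mean(!is.na(x2)) < min_call_fraction) next
    f1 <- .ofreq(x1); f2 <- .ofreq(x2)
    if (is.na(f1) || is.na(f2)) next
    for (al in c("ref", "alt")) {
      g1 <- if (al == "alt") f1 else 1 - f1
      g2 <- if (al == "alt") f2 else 1 - f2
      if (g2 == 0 && g1 > 0 && g1 < 1) {
        out[[length(out) + 1L]] <- data.frame(site = gm$sites$id[j],
                                              donor = lineages[1], allele = al)
      } else if (g1 == 0 && g2 > 0 && g2 < 1) {
        out[[length(out) + 1L]] <- data.frame(site = gm$sites$id[j],
                                              donor = lineages[2], allele = al)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(site = character(0), donor = character(0), allele = character(0))
}

# brute-force group-private-site scan (site monomorphic without the group)
oracle_drop_private <- function(gm, in_grp) {
  removed <- character(0)
  for (j in seq_len(n_sites(gm))) {
    fo <- .ofreq(gm$calls[!in_grp, j])
    fg <- .ofreq(gm$calls[in_grp, j])
    if (is.na(fo) || is.na(fg)) next
    if ((fo == 0 && fg > 0) || (fo == 1 && fg < 1)) {
      removed <- c(removed, gm$sites$id[j])
    }
  }
  removed
}

# brute-force target-vs-background private alleles with fixed/segregating split
oracle_group_private <- function(gm, t_ids, b_ids) {
  n_fixed <- 0L; n_seg <- 0L; sites <- character(0)
  for (j in seq_len(n_sites(gm))) {
    ft <- .ofreq(gm$calls[t_ids, j]); fb <- .ofreq(gm$calls[b_ids, j])
    if (is.na(ft) || is.na(fb)) next
    for (al in c("ref", "alt")) {
      gt <- if (al == "alt") ft else 1 - ft
      gb <- if (al == "alt") fb else 1 - fb
      if (gb == 0 && gt > 0) {
        sites <- c(sites, gm$sites$id[j])
        if (gt == 1) n_fixed <- n_fixed + 1L else n_seg <- n_seg + 1L
      }
    }
  }
  list(sites = sites, n_fixed = n_fixed, n_segregating = n_seg)
}

# brute-force site filter recount
oracle_filter_sites <- function(gm, maf_min, missing_max, het_max) {
  keep <- logical(n_sites(gm))
  for (j in seq_len(n_sites(gm))) {
    x <- gm$calls[, j]
    cc <- sum(!is.na(x))
    miss <- mean(is.na(x))
    if (cc == 0) { keep[j] <- miss <= missing_max; next }
    f <- sum(x, na.rm = TRUE) / (2 * cc)
    maf <- min(f, 1 - f)
    het <- sum(x == 1, na.rm = TRUE) / cc
    keep[j] <- maf >= maf_min && miss <= missing_max && het <= het_max
  }
  gm$sites$id[keep]
}

oracle_filter_samples <- function(gm, missing_max, het_max) {
  drop <- character(0)
  for (i in seq_len(n_samples(gm))) {
    x <- gm$calls[i, ]
    cc <- sum(!is.na(x))
    miss <- mean(is.na(x))
    het <- if (cc > 0) sum(x == 1, na.rm = TRUE) / cc else 0
    if (miss > missing_max || het > het_max) drop <- c(drop, sample_ids(gm)[i])
  }
  drop
}

# brute-force percent-segregating capture
oracle_capture <- function(gm, subset) {
  seg_full <- 0L; seg_both <- 0L
  for (j in seq_len(n_sites(gm))) {
    f <- .ofreq(gm$calls[, j])
    if (is.na(f) || f == 0 || f == 1) next
    seg_full <- seg_full + 1L
    fs <- .ofreq(gm$calls[subset, j])
    if (!is.na(fs) && fs > 0 && fs < 1) seg_both <- seg_both + 1L
  }
  100 * seg_both / seg_full
}

# independent two-sided Fisher p: explicit binomial-coefficient enumeration
# over the table's support (does not use dhyper)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  supp <- max(0, k - n):min(k, m)
  logp <- lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k)
  p <- exp(logp)
  sum(p[p <= p[supp == a] * (1 + 1e-7)])
}
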