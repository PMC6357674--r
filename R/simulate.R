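# Synthetic two-lineage panel generator with ground truth.
#
# The generator emulates the statistical structure of a post-QC GBS call set
# from a selfing species split into two deeply diverged lineages (L1, L2):
# Balding-Nichols lineage frequencies around a shared ancestral frequency,
# fully inbred genotypes with a small residual-heterozygosity leak, a
# bottlenecked derived panel ("wheat") founded from a few L2 haplotypes with
# a handful of planted L1 introgressions, and three kinds of planted
# inter-lineage hybrids: an F1, a recombinant-inbred mosaic (RIL), and a
# fixed "hybrid lineage" group carrying group-private alleles.

#' Simulation configuration
#'
#' Returns a validated configuration list for [simulate_panel()]. Defaults
#' describe a scaled-down two-lineage collection: 60 + 60 lineage accessions,
#' 20 derived (wheat-like) lines, and nine planted hybrids (one F1, one RIL,
#' and a seven-member hybrid-lineage group), genotyped at 2000 SNPs on seven
#' chromosomes.
#'
#' @param n_L1,n_L2,n_wheat Sample counts for the two lineages and the
#'   derived panel.
#' @param n_sites Number of SNP sites.
#' @param n_chromosomes Number of chromosomes the sites are spread over.
#' @param divergence_F Balding-Nichols divergence parameter in (0, 1); the
#'   expected Hudson F_ST between the two lineages.
#' @param residual_het Probability that a genotype's second allele is
#'   re-drawn from the lineage frequency (residual outcrossing/heterozygosity).
#' @param missing_rate Per-call missing probability, applied last.
#' @param error_rate Per-call probability of flipping a non-missing dosage to
#'   one of the other two states uniformly, applied after hybrid construction
#'   so the recorded truth stays clean.
#' @param n_f1 Number of planted F1 hybrids (parents drawn from the panel).
#' @param n_ril Number of planted recombinant-inbred mosaics.
#' @param ril_breakpoints_per_chrom Expected ancestry switches per chromosome
#'   for RIL mosaics (2-state Markov chain over site order).
#' @param hybrid_group_size Members of the fixed hybrid-lineage group (all
#'   copies of one shared prototype mosaic).
#' @param hybrid_private_fixed,hybrid_private_segregating Numbers of sites
#'   given a group-exclusive allele fixed in, or segregating within, the
#'   hybrid-lineage group.
#' @param hybrid_prototype_breakpoints_per_chrom Expected switches per
#'   chromosome of the hybrid-lineage prototype; much larger than the RIL
#'   value so the group shows the interleaved, low-clarity private-allele
#'   pattern of a lineage descended from multiple intercrossing generations.
#' @param wheat_founder_count Number of L2 haplotypes founding the derived
#'   panel (bottleneck).
#' @param wheat_introgression_sites Number of L1-private sites planted as
#'   introgressions into the derived panel.
#' @param wheat_introgression_carriers Carriers per planted introgression
#'   site (must be >= 2 so the consensus rule can recover them).
#' @param l1_cline_F,l2_cline_F Balding-Nichols parameters of a secondary
#'   within-lineage split (two subpopulations each); the L1 split is tied to
#'   a planted longitudinal gradient and the L2 split to an altitudinal one.
#'   Set to 0 for a pure two-population model.
#' @param seed Integer seed; all randomness flows from one generator, so the
#'   same configuration is bit-reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_L1 = 60, n_L2 = 60, n_wheat = 20,
                       n_sites = 2000, n_chromosomes = 7,
                       divergence_F = 0.55, residual_het = 0.002,
                       missing_rate = 0.03, error_rate = 0,
                       n_f1 = 1, n_ril = 1, ril_breakpoints_per_chrom = 3,
                       hybrid_group_size = 7, hybrid_private_fixed = 20,
                       hybrid_private_segregating = 5,
                       hybrid_prototype_breakpoints_per_chrom = 25,
                       wheat_founder_count = 4, wheat_introgression_sites = 8,
                       wheat_introgression_carriers = 3,
                       l1_cline_F = 0.12, l2_cline_F = 0.06, seed = 1) {
  cfg <- list(n_L1 = n_L1, n_L2 = n_L2, n_wheat = n_wheat, n_sites = n_sites,
              n_chromosomes = n_chromosomes, divergence_F = divergence_F,
              residual_het = residual_het, missing_rate = missing_rate,
              error_rate = error_rate, n_f1 = n_f1, n_ril = n_ril,
              ril_breakpoints_per_chrom = ril_breakpoints_per_chrom,
              hybrid_group_size = hybrid_group_size,
              hybrid_private_fixed = hybrid_private_fixed,
              hybrid_private_segregating = hybrid_private_segregating,
              hybrid_prototype_breakpoints_per_chrom =
                hybrid_prototype_breakpoints_per_chrom,
              wheat_founder_count = wheat_founder_count,
              wheat_introgression_sites = wheat_introgression_sites,
              wheat_introgression_carriers = wheat_introgression_carriers,
              l1_cline_F = l1_cline_F, l2_cline_F = l2_cline_F, seed = seed)
  counts <- c("n_L1", "n_L2", "n_wheat", "n_sites", "n_chromosomes", "n_f1",
              "n_ril", "hybrid_group_size", "hybrid_private_fixed",
              "hybrid_private_segregating", "wheat_founder_count",
              "wheat_introgression_sites", "wheat_introgression_carriers")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != round(v)) {
      stop(nm, " must be a non-negative integer")
    }
    cfg[[nm]] <- as.integer(v)
  }
  for (nm in c("residual_het", "missing_rate", "error_rate")) {
    .assert_prob(cfg[[nm]], nm)
  }
  if (divergence_F <= 0 || divergence_F >= 1) {
    stop("divergence_F must lie in the open interval (0, 1)")
  }
  for (nm in c("l1_cline_F", "l2_cline_F")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] >= 1) stop(nm, " must lie in [0, 1)")
  }
  if (cfg$n_L1 < 1 || cfg$n_L2 < 1) stop("both lineages need at least 1 sample")
  if (cfg$n_sites < cfg$n_chromosomes) stop("need at least one site per chromosome")
  if (cfg$wheat_introgression_sites > 0 && cfg$wheat_introgression_carriers < 2) {
    stop("wheat_introgression_carriers must be >= 2")
  }
  if (cfg$wheat_introgression_sites > 0 &&
      cfg$wheat_introgression_carriers > cfg$n_wheat) {
    stop("wheat_introgression_carriers exceeds n_wheat")
  }
  if (cfg$wheat_founder_count > cfg$n_L2) {
    stop("wheat_founder_count exceeds n_L2")
  }
  if (cfg$n_wheat > 0 && cfg$wheat_founder_count < 1) {
    stop("need at least one wheat founder")
  }
  if (cfg$hybrid_group_size == 1 && cfg$hybrid_private_segregating > 0) {
    stop("segregating group-private alleles need a group of >= 2")
  }
  structure(cfg, class = "sim_config")
}

# Balding-Nichols draw around frequency p with divergence F; degenerate
# frequencies stay fixed.
.bn_draw <- function(p, F) {
  if (F <= 0) return(p)
  q <- p
  ok <- p > 0 & p < 1
  a <- p[ok] * (1 - F) / F
  b <- (1 - p[ok]) * (1 - F) / F
  q[ok] <- stats::rbeta(sum(ok), a, b)
  q
}

# inbred genotypes: one allele drawn from q and duplicated; with probability
# `het` the second allele is re-drawn independently
.gen_inbred <- function(n_ind, q, het) {
  m <- length(q)
  a1 <- matrix(stats::rbinom(n_ind * m, 1L, rep(q, each = n_ind)), nrow = n_ind)
  g <- 2L * a1
  if (het > 0) {
    redraw <- matrix(stats::rbinom(n_ind * m, 1L, het), nrow = n_ind) == 1L
    if (any(redraw)) {
      a2 <- matrix(stats::rbinom(n_ind * m, 1L, rep(q, each = n_ind)), nrow = n_ind)
      g[redraw] <- a1[redraw] + a2[redraw]
    }
  }
  g
}

# one gamete per site from an unphased diploid dosage vector
.gamete <- function(g) {
  out <- integer(length(g))
  out[g == 2L] <- 1L
  het <- g == 1L
  if (any(het)) out[het] <- stats::rbinom(sum(het), 1L, 0.5)
  out
}

# 2-state Markov ancestry over site order, per chromosome
.mosaic_ancestry <- function(chrom, bp_per_chrom) {
  anc <- integer(length(chrom))
  for (cr in unique(chrom)) {
    idx <- which(chrom == cr)
    m <- length(idx)
    s <- if (m > 1) min(1, bp_per_chrom / (m - 1)) else 0
    state <- sample(c(1L, 2L), 1L)
    a <- integer(m)
    a[1] <- state
    if (m > 1) {
      flips <- stats::runif(m - 1) < s
      for (k in 2:m) {
        if (flips[k - 1]) state <- 3L - state
        a[k] <- state
      }
    }
    anc[idx] <- a
  }
  anc
}

# homozygous mosaic genotype from two parents; parental het sites are fixed
# to a random homozygote (selfing to homozygosity)
.mosaic_genotype <- function(anc, g1, g2) {
  g <- ifelse(anc == 1L, g1, g2)
  het <- g == 1L
  if (any(het)) g[het] <- 2L * stats::rbinom(sum(het), 1L, 0.5)
  g
}

#' Simulate a two-lineage SNP panel with ground truth
#'
#' Generates a genotype matrix, passport table, phenotype table and a truth
#' record under the model described in [sim_config()]. Identical seeds give
#' bit-identical output.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{geno}{[genotype_matrix()] of all samples.}
#'     \item{passport}{Data frame (`id`, `group`, `country`, `longitude`,
#'       `latitude`, `altitude`); all nine hybrids carry group label
#'       `"hybrid"`.}
#'     \item{phenotypes}{Binary trait table (`R`/`S`/missing) with
#'       lineage-biased resistance rates.}
#'     \item{truth}{Ground truth: per-sample true group, subpopulation and
#'       parent ids; per-mosaic per-site ancestry and breakpoint counts;
#'       planted introgression sites with carrier ids; planted hybrid-group
#'       private sites.}
#'     \item{config}{The configuration used.}
#'   }
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  ## -- sites ---------------------------------------------------------------
  per_chrom <- diff(round(seq(0, cfg$n_sites, length.out = cfg$n_chromosomes + 1)))
  chrom_names <- paste0(seq_len(cfg$n_chromosomes), "D")
  chrom <- rep(chrom_names, per_chrom)
  pos <- unlist(lapply(per_chrom, function(k) sort(sample.int(5e8L, k))))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  sites <- data.frame(id = sprintf("S%05d", seq_len(cfg$n_sites)), chrom = chrom,
                      pos = pos, ref = ref, alt = unname(alt),
                      stringsAsFactors = FALSE)

  ## -- lineage allele frequencies ------------------------------------------
  p_anc <- stats::runif(cfg$n_sites, 0.1, 0.9)
  q_L1 <- .bn_draw(p_anc, cfg$divergence_F)
  q_L2 <- .bn_draw(p_anc, cfg$divergence_F)

  split_counts <- function(n) c(ceiling(n / 2), floor(n / 2))
  gen_lineage <- function(n, q, cline_F) {
    if (cline_F > 0 && n >= 2) {
      ns <- split_counts(n)
      qa <- .bn_draw(q, cline_F)
      qb <- .bn_draw(q, cline_F)
      g <- rbind(.gen_inbred(ns[1], qa, cfg$residual_het),
                 .gen_inbred(ns[2], qb, cfg$residual_het))
      list(g = g, subpop = rep(c("a", "b"), ns))
    } else {
      list(g = .gen_inbred(n, q, cfg$residual_het), subpop = rep("a", n))
    }
  }
  l1 <- gen_lineage(cfg$n_L1, q_L1, cfg$l1_cline_F)
  l2 <- gen_lineage(cfg$n_L2, q_L2, cfg$l2_cline_F)
  id_L1 <- sprintf("L1_%03d", seq_len(cfg$n_L1))
  id_L2 <- sprintf("L2_%03d", seq_len(cfg$n_L2))

  ## -- derived (wheat-like) panel: bottleneck from a few L2 haplotypes ------
  wheat <- matrix(integer(0), nrow = 0, ncol = cfg$n_sites)
  id_wheat <- character(0)
  founders <- integer(0)
  if (cfg$n_wheat > 0) {
    founders <- sort(sample.int(cfg$n_L2, cfg$wheat_founder_count))
    q_pool <- colMeans(l2$g[founders, , drop = FALSE]) / 2
    q_wheat <- .bn_draw(q_pool, cfg$divergence_F)
    wheat <- .gen_inbred(cfg$n_wheat, q_wheat, cfg$residual_het)
    id_wheat <- sprintf("WHT_%03d", seq_len(cfg$n_wheat))
  }

  ## -- planted L1 introgressions into the derived panel ---------------------
  f_l1 <- colMeans(l1$g) / 2
  f_l2 <- colMeans(l2$g) / 2
  # realized L1-private alleles: segregating in L1, absent from L2
  l1_priv_alt <- f_l2 == 0 & f_l1 > 0 & f_l1 < 1
  l1_priv_ref <- f_l2 == 1 & f_l1 > 0 & f_l1 < 1
  intro <- NULL
  if (cfg$wheat_introgression_sites > 0) {
    if (cfg$n_wheat == 0) stop("introgression sites require n_wheat > 0")
    cand <- which(l1_priv_alt | l1_priv_ref)
    # carriers must introduce the allele, so it must be absent from wheat too
    cand <- cand[vapply(cand, function(s) {
      if (l1_priv_alt[s]) all(wheat[, s] == 0L) else all(wheat[, s] == 2L)
    }, logical(1))]
    if (length(cand) < cfg$wheat_introgression_sites) {
      stop("infeasible configuration: only ", length(cand),
           " realized L1-private sites available for introgression planting")
    }
    pick <- sort(sample(cand, cfg$wheat_introgression_sites))
    carriers <- lapply(pick, function(s) sort(sample.int(cfg$n_wheat,
                                        cfg$wheat_introgression_carriers)))
    for (k in seq_along(pick)) {
      s <- pick[k]
      wheat[carriers[[k]], s] <- if (l1_priv_alt[s]) 2L else 0L
    }
    intro <- data.frame(site = sites$id[pick],
                        allele = ifelse(l1_priv_alt[pick], "alt", "ref"),
                        carriers = vapply(carriers, function(ix)
                          paste(id_wheat[ix], collapse = ","), character(1)),
                        stringsAsFactors = FALSE)
  }

  ## -- planted hybrids -------------------------------------------------------
  pick_parents <- function() {
    c(sample.int(cfg$n_L1, 1L), sample.int(cfg$n_L2, 1L))
  }
  truth_samples <- data.frame(id = c(id_L1, id_L2, id_wheat),
                              true_group = c(rep("L1", cfg$n_L1),
                                             rep("L2", cfg$n_L2),
                                             rep("wheat", cfg$n_wheat)),
                              subpop = c(l1$subpop, l2$subpop,
                                         rep(NA_character_, cfg$n_wheat)),
                              parent1 = NA_character_, parent2 = NA_character_,
                              stringsAsFactors = FALSE)
  hyb_calls <- list()
  hyb_truth <- list()
  ancestry <- list()
  breakpoints <- list()

  for (k in seq_len(cfg$n_f1)) {
    pp <- pick_parents()
    g <- .gamete(l1$g[pp[1], ]) + .gamete(l2$g[pp[2], ])
    id <- sprintf("HYB_F1_%02d", k)
    hyb_calls[[id]] <- g
    hyb_truth[[id]] <- c("F1", id_L1[pp[1]], id_L2[pp[2]])
  }
  for (k in seq_len(cfg$n_ril)) {
    pp <- pick_parents()
    anc <- .mosaic_ancestry(chrom, cfg$ril_breakpoints_per_chrom)
    g <- .mosaic_genotype(anc, l1$g[pp[1], ], l2$g[pp[2], ])
    id <- sprintf("HYB_RIL_%02d", k)
    hyb_calls[[id]] <- g
    hyb_truth[[id]] <- c("RIL", id_L1[pp[1]], id_L2[pp[2]])
    ancestry[[id]] <- anc
    breakpoints[[id]] <- tapply(anc, chrom, function(a) sum(diff(a) != 0))
  }
  hybrid_private <- NULL
  if (cfg$hybrid_group_size > 0) {
    pp <- pick_parents()
    anc <- .mosaic_ancestry(chrom, cfg$hybrid_prototype_breakpoints_per_chrom)
    proto <- .mosaic_genotype(anc, l1$g[pp[1], ], l2$g[pp[2], ])
    ids <- sprintf("HYBG_%02d", seq_len(cfg$hybrid_group_size))
    for (id in ids) {
      hyb_calls[[id]] <- proto
      hyb_truth[[id]] <- c("hybrid_lineage", id_L1[pp[1]], id_L2[pp[2]])
      ancestry[[id]] <- anc
      breakpoints[[id]] <- tapply(anc, chrom, function(a) sum(diff(a) != 0))
    }
    # group-exclusive alleles: planted at sites monomorphic in everyone else
    n_priv <- cfg$hybrid_private_fixed + cfg$hybrid_private_segregating
    if (n_priv > 0) {
      others <- rbind(l1$g, l2$g, wheat,
                      do.call(rbind, hyb_calls[setdiff(names(hyb_calls), ids)]))
      mono0 <- colSums(others != 0L) == 0L & proto == 0L
      mono2 <- colSums(others != 2L) == 0L & proto == 2L
      cand <- which(mono0 | mono2)
      if (length(cand) < n_priv) {
        stop("infeasible configuration: only ", length(cand),
             " monomorphic sites available for hybrid-group private alleles")
      }
      pick <- sort(sample(cand, n_priv))
      fixed_sites <- pick[seq_len(cfg$hybrid_private_fixed)]
      seg_sites <- setdiff(pick, fixed_sites)
      for (s in fixed_sites) {
        val <- if (mono0[s]) 2L else 0L
        for (id in ids) hyb_calls[[id]][s] <- val
      }
      for (s in seg_sites) {
        repeat {
          carry <- stats::rbinom(cfg$hybrid_group_size, 1L, 0.5)
          if (sum(carry) > 0 && sum(carry) < cfg$hybrid_group_size) break
        }
        for (j in seq_along(ids)) {
          base <- if (mono0[s]) 0L else 2L
          flip <- if (mono0[s]) 2L else 0L
          hyb_calls[[ids[j]]][s] <- if (carry[j] == 1L) flip else base
        }
      }
      hybrid_private <- list(fixed = sites$id[fixed_sites],
                             segregating = sites$id[seg_sites])
    }
  }

  ## -- assemble, then error and missingness ---------------------------------
  calls <- rbind(l1$g, l2$g, wheat,
                 if (length(hyb_calls)) do.call(rbind, hyb_calls))
  ids_all <- c(id_L1, id_L2, id_wheat, names(hyb_calls))
  rownames(calls) <- ids_all
  if (length(hyb_calls)) {
    ht <- do.call(rbind, hyb_truth)
    truth_samples <- rbind(truth_samples,
                           data.frame(id = names(hyb_calls), true_group = ht[, 1],
                                      subpop = NA_character_, parent1 = ht[, 2],
                                      parent2 = ht[, 3], stringsAsFactors = FALSE))
  }
  storage.mode(calls) <- "integer"
  if (cfg$error_rate > 0) {
    flip <- which(stats::rbinom(length(calls), 1L, cfg$error_rate) == 1L)
    if (length(flip)) {
      shift <- sample(1:2, length(flip), replace = TRUE)
      calls[flip] <- (calls[flip] + shift) %% 3L
    }
  }
  if (cfg$missing_rate > 0) {
    drop <- stats::rbinom(length(calls), 1L, cfg$missing_rate) == 1L
    calls[drop] <- NA_integer_
  }
  geno <- genotype_matrix(calls, sites)

  ## -- passport: planted geographic clines ----------------------------------
  group_label <- ifelse(truth_samples$true_group %in%
                          c("F1", "RIL", "hybrid_lineage"),
                        "hybrid", truth_samples$true_group)
  np <- nrow(truth_samples)
  passport <- data.frame(id = truth_samples$id, group = group_label,
                         country = NA_character_, longitude = NA_real_,
                         latitude = NA_real_, altitude = NA_real_,
                         stringsAsFactors = FALSE)
  is_l1 <- truth_samples$true_group == "L1"
  is_l2 <- truth_samples$true_group == "L2"
  west <- is_l1 & truth_samples$subpop == "a"
  east <- is_l1 & truth_samples$subpop == "b"
  passport$longitude[west] <- stats::runif(sum(west), 38, 50)
  passport$longitude[east] <- stats::runif(sum(east), 53, 82)
  passport$latitude[is_l1] <- stats::runif(sum(is_l1), 33, 42)
  passport$altitude[is_l1] <- stats::runif(sum(is_l1), 600, 2500)
  passport$country[is_l1] <- sample(c("Iran", "Afghanistan", "Azerbaijan",
                                      "Tajikistan", "Turkey", "China"),
                                    sum(is_l1), replace = TRUE)
  low <- is_l2 & truth_samples$subpop == "a"
  high <- is_l2 & truth_samples$subpop == "b"
  passport$altitude[low] <- stats::runif(sum(low), -20, 140)
  passport$altitude[high] <- stats::runif(sum(high), 160, 1600)
  passport$longitude[is_l2] <- stats::runif(sum(is_l2), 44, 56)
  passport$latitude[is_l2] <- stats::runif(sum(is_l2), 35, 42)
  passport$country[is_l2] <- sample(c("Iran", "Azerbaijan", "Armenia", "Georgia"),
                                    sum(is_l2), replace = TRUE)
  is_wheat <- truth_samples$true_group == "wheat"
  passport$country[is_wheat] <- "USA"
  is_hg <- truth_samples$true_group == "hybrid_lineage"
  passport$country[is_hg] <- "Georgia"
  passport$longitude[is_hg] <- stats::runif(sum(is_hg), 41.5, 46.5)
  passport$latitude[is_hg] <- stats::runif(sum(is_hg), 41, 43.5)
  passport$altitude[is_hg] <- stats::runif(sum(is_hg), 200, 1200)
  is_f1 <- truth_samples$true_group == "F1"
  passport$country[is_f1] <- "Turkmenistan"
  passport$longitude[is_f1] <- stats::runif(sum(is_f1), 53, 66)
  passport$latitude[is_f1] <- stats::runif(sum(is_f1), 35, 42)
  passport$altitude[is_f1] <- stats::runif(sum(is_f1), 100, 800)

  ## -- phenotypes: lineage-biased binary resistance traits ------------------
  traits <- c("leaf_rust", "stem_rust_ttksk", "hessian_fly")
  p_res <- c(L1 = 0.45, L2 = 0.30, wheat = 0.10, F1 = 0.35, RIL = 0.35,
             hybrid_lineage = 0.35)
  phenotypes <- data.frame(id = truth_samples$id, stringsAsFactors = FALSE)
  for (tr in traits) {
    pr <- p_res[truth_samples$true_group]
    val <- ifelse(stats::rbinom(np, 1L, pr) == 1L, "R", "S")
    val[stats::rbinom(np, 1L, 0.1) == 1L] <- NA_character_
    phenotypes[[tr]] <- val
  }

  truth <- list(samples = truth_samples,
                ancestry = ancestry,
                breakpoints = breakpoints,
                introgression = intro,
                hybrid_private = hybrid_private,
                wheat_founders = if (length(founders)) id_L2[founders] else character(0),
                site_order = sites$id)
  list(geno = geno, passport = passport, phenotypes = phenotypes,
       truth = truth, config = cfg)
}

#' Write a simulated panel as a plain-text fixture
#'
#' Writes `panel.vcf`, `passport.tsv`, `phenotypes.tsv`, `truth_samples.tsv`,
#' `truth_sites.tsv` (planted introgression and hybrid-group private sites)
#' and `truth_ancestry.tsv` (per-site ancestry of mosaic samples) to a
#' directory. Byte-identical across runs with the same configuration.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @param force Overwrite into a non-empty directory.
#' @return Character vector of file paths, invisibly.
#' @export
write_fixture <- function(cfg, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop("output directory is not empty (use force = TRUE): ", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_panel(cfg)
  paths <- file.path(out_dir, c("panel.vcf", "passport.tsv", "phenotypes.tsv",
                                "truth_samples.tsv", "truth_sites.tsv",
                                "truth_ancestry.tsv"))
  write_vcf(sim$geno, paths[1])
  .write_tsv(sim$passport, paths[2])
  .write_tsv(sim$phenotypes, paths[3])
  .write_tsv(sim$truth$samples, paths[4])

  site_rows <- list()
  if (!is.null(sim$truth$introgression)) {
    site_rows[[1]] <- cbind(role = "introgression", sim$truth$introgression)
  }
  hp <- sim$truth$hybrid_private
  if (!is.null(hp)) {
    site_rows[[2]] <- data.frame(role = rep(c("hybrid_private_fixed",
                                              "hybrid_private_segregating"),
                                            c(length(hp$fixed), length(hp$segregating))),
                                 site = c(hp$fixed, hp$segregating),
                                 allele = NA_character_, carriers = NA_character_,
                                 stringsAsFactors = FALSE)
  }
  st <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(role = character(0), site = character(0),
               allele = character(0), carriers = character(0))
  .write_tsv(st, paths[5])

  anc <- sim$truth$ancestry
  if (length(anc)) {
    ad <- data.frame(sample = rep(names(anc), each = length(sim$truth$site_order)),
                     site = rep(sim$truth$site_order, length(anc)),
                     ancestry = unlist(anc, use.names = FALSE))
  } else {
    ad <- data.frame(sample = character(0), site = character(0),
                     ancestry = integer(0))
  }
  .write_tsv(ad, paths[6])
  invisible(paths)
}

#' Configuration of the small fixture shipped with the package
#'
#' A reduced panel (36 samples, 200 sites, 3 chromosomes) used for examples
#' and shipped under `inst/extdata/`; the full default panel is generated at
#' run time with [sim_config()].
#'
#' @return A [sim_config()].
#' @export
example_fixture_config <- function() {
  sim_config(n_L1 = 12, n_L2 = 12, n_wheat = 5, n_sites = 200,
             n_chromosomes = 3, n_f1 = 1, n_ril = 1, hybrid_group_size = 5,
             hybrid_private_fixed = 6, hybrid_private_segregating = 2,
             wheat_founder_count = 3, wheat_introgression_sites = 4,
             wheat_introgression_carriers = 2, seed = 20190125)
}
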