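#' Construct a genotype matrix
#'
#' The central data container of the package: diploid biallelic genotypes
#' stored as alternate-allele dosages in \{0, 1, 2\} with `NA` as the missing
#' sentinel, together with per-site metadata. Sites are re-sorted by
#' (chromosome, position) on construction, ties broken by site id, so all
#' downstream positional operations (painting, BED export) see genomic order.
#'
#' @param calls Integer matrix, samples in rows, sites in columns. Values must
#'   be 0, 1, 2 or `NA`. Row names are sample ids, column names site ids (both
#'   may be supplied through `samples` / `sites` instead).
#' @param sites Data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`;
#'   one row per column of `calls`. `pos` is 1-based. `ref` and `alt` must be
#'   distinct single bases.
#' @param samples Optional character vector of sample ids (defaults to
#'   `rownames(calls)`).
#' @return An object of class `geno_matrix`: a list with elements `calls`
#'   (dosage matrix with dimnames) and `sites` (site metadata data frame).
#' @examples
#' gm <- genotype_matrix(
#'   rbind(A = c(0L, 1L), B = c(2L, NA)),
#'   data.frame(id = c("s1", "s2"), chrom = "1D", pos = c(100L, 50L),
#'              ref = "A", alt = c("G", "T"))
#' )
#' gm$sites$id  # sorted by position: s2 first
#' @export
genotype_matrix <- function(calls, sites, samples = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (!all(calls %in% c(0L, 1L, 2L, NA_integer_))) {
    stop("calls must contain only dosages 0, 1, 2 or NA")
  }
  samples <- samples %||% rownames(calls)
  if (is.null(samples)) stop("sample ids required (rownames or 'samples')")
  samples <- as.character(samples)
  if (length(samples) != nrow(calls)) stop("length(samples) != nrow(calls)")
  if (anyDuplicated(samples)) stop("duplicate sample ids")

  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites))) {
    stop("sites needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(sites) != ncol(calls)) stop("nrow(sites) != ncol(calls)")
  sites$id <- as.character(sites$id)
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (anyDuplicated(sites$id)) stop("duplicate site ids")
  if (any(sites$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")

  ord <- order(sites$chrom, sites$pos, sites$id)
  sites <- sites[ord, need, drop = FALSE]
  rownames(sites) <- NULL
  calls <- calls[, ord, drop = FALSE]
  dimnames(calls) <- list(samples, sites$id)
  structure(list(calls = calls, sites = sites), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d sites on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$sites$chrom))))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing: %.2f%%  het calls: %.2f%%\n",
              100 * miss, 100 * mean(x$calls == 1L, na.rm = TRUE)))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x `geno_matrix`.
#' @param i Sample ids or indices (rows).
#' @param j Site ids or indices (columns).
#' @param ... Ignored.
#' @return A new `geno_matrix` restricted to the requested samples/sites.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  calls <- x$calls[i, j, drop = FALSE]
  jj <- match(colnames(calls), x$sites$id)
  genotype_matrix(calls, x$sites[jj, , drop = FALSE])
}

#' Sample ids of a genotype matrix
#' @param gm `geno_matrix`.
#' @return Character vector of sample ids in matrix order.
#' @export
sample_ids <- function(gm) rownames(gm$calls)

#' Number of samples / sites
#' @param gm `geno_matrix`.
#' @return Integer.
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' @rdname n_samples
#' @export
n_sites <- function(gm) ncol(gm$calls)

#' Swap reference and alternate alleles at selected sites
#'
#' Dosages map involutively d -> 2 - d for non-missing calls; missing stays
#' missing. Mostly useful for testing the dosage-orientation invariants.
#'
#' @param gm `geno_matrix`.
#' @param sites Site ids to swap (default all).
#' @return A `geno_matrix` with the selected sites re-oriented.
#' @export
swap_alleles <- function(gm, sites = NULL) {
  sites <- sites %||% gm$sites$id
  j <- match(sites, gm$sites$id)
  if (anyNA(j)) stop("unknown site id(s)")
  calls <- gm$calls
  calls[, j] <- 2L - calls[, j]
  meta <- gm$sites
  tmp <- meta$ref[j]
  meta$ref[j] <- meta$alt[j]
  meta$alt[j] <- tmp
  genotype_matrix(calls, meta)
}
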