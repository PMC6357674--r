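# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce a passport table or named vector to a sample partition
#'
#' A partition maps every sample id to exactly one group label. It is the
#' grouping object consumed by all group-wise statistics.
#'
#' @param x Either a data frame with `id` and `group` columns (e.g. the result
#'   of [read_passport()]) or a named character vector (names = sample ids,
#'   values = group labels).
#' @return Named character vector mapping sample id to group.
#' @export
as_partition <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("id", "group") %in% names(x))) {
      stop("data frame partition needs 'id' and 'group' columns")
    }
    p <- stats::setNames(as.character(x$group), as.character(x$id))
  } else if (is.character(x) && !is.null(names(x))) {
    p <- x
  } else {
    stop("partition must be a passport data frame or a named character vector")
  }
  if (anyDuplicated(names(p))) stop("duplicate sample ids in partition")
  if (any(is.na(p) | p == "")) stop("every sample must map to a group")
  p
}

#' Sample ids belonging to one group of a partition
#'
#' @param partition Named character vector from [as_partition()].
#' @param group Group label.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(partition, group) {
  partition <- as_partition(partition)
  if (!group %in% partition) stop("unknown group: ", group)
  names(partition)[partition == group]
}

# allele frequency of the alternate allele over non-missing calls
.allele_freq <- function(calls) {
  cc <- colSums(!is.na(calls))
  s <- colSums(calls, na.rm = TRUE)
  f <- ifelse(cc > 0, s / (2 * cc), NA_real_)
  list(freq = f, n_call = cc)
}

.assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(name, " must be a probability in [0, 1]")
  }
}
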