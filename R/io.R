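# Readers and writers for the exchange formats the pipeline consumes:
# VCF v4.x (GT field only), HapMap-style genotype tables, passport and
# phenotype TSVs. All writers are byte-deterministic (no timestamps).

.IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

#' Read a VCF file into a genotype matrix
#'
#' Only biallelic SNP records are kept; multiallelic or non-SNP records are
#' skipped and counted. GT fields are mapped to alternate-allele dosage
#' (`0/0` -> 0, `0/1` or `1/0` -> 1, `1/1` -> 2, `./.` -> missing); phase
#' separators (`|`) are accepted and ignored, as the panel model is unphased.
#'
#' @param path Path to a VCF v4.x file (plain or gzipped).
#' @return A [genotype_matrix()] with attribute `n_skipped` giving the number
#'   of skipped non-biallelic-SNP records.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no records in VCF: ", path)
  bases <- c("A", "C", "G", "T")
  keep <- fix$REF %in% bases & fix$ALT %in% bases
  n_skipped <- sum(!keep)
  if (!any(keep)) stop("no biallelic SNP records in VCF: ", path)

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  gt_clean <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow = nrow(gt_clean), ncol = ncol(gt_clean))
  dos[gt_clean == "0/0"] <- 0L
  dos[gt_clean %in% c("0/1", "1/0")] <- 1L
  dos[gt_clean == "1/1"] <- 2L

  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  sites <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  gm <- genotype_matrix(t(dos), sites, samples = colnames(gt))
  attr(gm, "n_skipped") <- n_skipped
  if (n_skipped > 0) {
    message("read_vcf: skipped ", n_skipped, " non-biallelic-SNP record(s)")
  }
  gm
}

#' Write a genotype matrix as VCF v4.2
#'
#' GT-only FORMAT; missing calls written as `./.`. Output is byte-stable for
#' a given matrix (no date or environment lines in the header).
#'
#' @param gm `geno_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  calls <- gm$calls
  body <- vapply(seq_len(ncol(calls)), function(j) {
    g <- calls[, j]
    s <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(s, collapse = "\t")
  }, character(1))
  st <- gm$sites
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=lineagescope",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(calls)), collapse = "\t"),
    paste(st$chrom, st$pos, st$id, st$ref, st$alt, ".", "PASS", ".", "GT",
          body, sep = "\t")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

.hapmap_cols <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                  "center", "protLSID", "assayLSID", "panelLSID", "QCcode")

#' Read a HapMap-style genotype table
#'
#' Tab-separated with the standard 11 leading columns (`rs#`, `alleles`,
#' `chrom`, `pos`, ...) followed by one column per sample. Genotype codes may
#' be single-letter IUPAC (hets as R/Y/S/W/K/M) or two-letter pairs ("AG");
#' "N"/"NN" are missing. Dosage counts the second allele of the `alleles`
#' field (ref/alt order).
#'
#' @param path Path to the file.
#' @return A [genotype_matrix()].
#' @export
read_hapmap <- function(path) {
  if (!file.exists(path)) stop("cannot read HapMap file: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 12) stop("HapMap format error: fewer than 12 columns")
  n_fixed <- length(.hapmap_cols)
  samples <- names(raw)[(n_fixed + 1):ncol(raw)]
  al <- strsplit(raw$alleles, "/", fixed = TRUE)
  if (any(lengths(al) != 2)) stop("HapMap format error: bad alleles field")
  ref <- vapply(al, `[`, character(1), 1)
  alt <- vapply(al, `[`, character(1), 2)

  decode <- function(code, ref_a, alt_a) {
    if (is.na(code) || code %in% c("N", "NN", "", "--")) return(NA_integer_)
    if (nchar(code) == 1) {
      if (code %in% names(.IUPAC_HET)) {
        pair <- strsplit(.IUPAC_HET[[code]], "")[[1]]
      } else {
        pair <- c(code, code)
      }
    } else if (nchar(code) == 2) {
      pair <- strsplit(code, "")[[1]]
    } else {
      stop("HapMap format error: genotype code '", code, "'")
    }
    if (!all(pair %in% c(ref_a, alt_a))) return(NA_integer_)
    sum(pair == alt_a)
  }
  dos <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(raw))
  for (j in seq_len(nrow(raw))) {
    codes <- as.character(raw[j, (n_fixed + 1):ncol(raw)])
    dos[, j] <- vapply(codes, decode, integer(1), ref_a = ref[j], alt_a = alt[j])
  }
  sites <- data.frame(id = raw[["rs#"]], chrom = raw$chrom,
                      pos = as.integer(raw$pos), ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  genotype_matrix(dos, sites, samples = samples)
}

#' Write a genotype matrix as a HapMap-style table
#'
#' Two-letter genotype codes; missing as "NN".
#'
#' @param gm `geno_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hapmap <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  st <- gm$sites
  calls <- gm$calls
  body <- vapply(seq_len(ncol(calls)), function(j) {
    g <- calls[, j]
    code <- character(length(g))
    code[is.na(g)] <- "NN"
    code[!is.na(g) & g == 0L] <- strrep(st$ref[j], 2)
    code[!is.na(g) & g == 1L] <- paste0(st$ref[j], st$alt[j])
    code[!is.na(g) & g == 2L] <- strrep(st$alt[j], 2)
    paste(code, collapse = "\t")
  }, character(1))
  header <- paste(c(.hapmap_cols, rownames(calls)), collapse = "\t")
  lines <- c(header,
             paste(st$id, paste0(st$ref, "/", st$alt), st$chrom, st$pos,
                   "+", "NA", "NA", "NA", "NA", "NA", "NA", body, sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a sample passport table
#'
#' TSV with header columns `id`, `group`, `country`, `longitude`, `latitude`,
#' `altitude`; blank fields are missing. Coordinates are validated
#' (|latitude| <= 90, |longitude| <= 180) and duplicate ids rejected.
#'
#' @param path Path to the TSV.
#' @return Data frame, one row per sample.
#' @export
read_passport <- function(path) {
  if (!file.exists(path)) stop("cannot read passport file: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("id", "group", "country", "longitude", "latitude", "altitude")
  if (!all(need %in% names(d))) {
    stop("passport file needs columns: ", paste(need, collapse = ", "))
  }
  d <- d[, need]
  d$id <- as.character(d$id)
  if (anyDuplicated(d$id)) stop("duplicate sample id(s) in passport file")
  for (col in c("longitude", "latitude", "altitude")) {
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  }
  if (any(abs(d$latitude) > 90, na.rm = TRUE)) {
    stop("latitude out of range [-90, 90]")
  }
  if (any(abs(d$longitude) > 180, na.rm = TRUE)) {
    stop("longitude out of range [-180, 180]")
  }
  d
}

#' Write a passport table
#' @param passport Data frame as returned by [read_passport()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_passport <- function(passport, path) {
  .write_tsv(passport, path)
}

#' Read a binary phenotype table
#'
#' TSV with an `id` column followed by one column per trait; values are
#' "R" (resistant), "S" (susceptible) or blank for missing.
#'
#' @param path Path to the TSV.
#' @return Data frame with `id` plus one character column per trait.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("cannot read phenotype file: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!"id" %in% names(d)) stop("phenotype file needs an 'id' column")
  if (anyDuplicated(names(d))) stop("duplicate trait names")
  d$id <- as.character(d$id)
  if (anyDuplicated(d$id)) stop("duplicate sample id(s) in phenotype file")
  bad <- setdiff(unlist(d[setdiff(names(d), "id")]), c("R", "S", NA))
  if (length(bad)) stop("phenotype scores must be 'R', 'S' or missing")
  d
}

#' Write a phenotype table
#' @param phenotypes Data frame as returned by [read_phenotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  .write_tsv(phenotypes, path)
}

# deterministic TSV writer (LF endings, no quoting)
.write_tsv <- function(d, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
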