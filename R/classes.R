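#' Genotype matrix container
#'
#' Holds SNP dosages (lines x markers, coded 0/1/2 with `NA` for missing
#' calls) together with optional marker map information. Rows are lines,
#' columns are markers; both must be uniquely named.
#'
#' @param dosage numeric matrix of allele dosages in \{0, 1, 2\} or `NA`,
#'   with line IDs as rownames and marker IDs as colnames.
#' @param chrom optional integer vector of chromosome indices per marker.
#' @param pos optional numeric vector of map positions (Morgan) per marker.
#' @param allele_freq optional numeric vector of the allele frequencies the
#'   markers were simulated from (kept by the simulator so that frequency
#'   recovery can be checked).
#'
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, chrom = NULL, pos = NULL, allele_freq = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("dosage must have line IDs as rownames and marker IDs as colnames")
  if (anyDuplicated(rownames(dosage)) || anyDuplicated(colnames(dosage)))
    stop("line and marker IDs must be unique")
  ok <- dosage[!is.na(dosage)]
  if (length(ok) && any(ok < 0 | ok > 2))
    stop("dosages must lie in [0, 2]")
  if (!is.null(chrom) && length(chrom) != ncol(dosage))
    stop("chrom must have one entry per marker")
  if (!is.null(pos) && length(pos) != ncol(dosage))
    stop("pos must have one entry per marker")
  structure(
    list(dosage = dosage, chrom = chrom, pos = pos, allele_freq = allele_freq),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$dosage))
  cat(sprintf(
    "geno_matrix: %d lines x %d markers (%.2f%% missing)\n",
    nrow(x$dosage), ncol(x$dosage), 100 * nmiss / length(x$dosage)
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Line IDs of a genotype matrix
#' @param geno a `geno_matrix`.
#' @return character vector of line IDs.
#' @export
line_ids <- function(geno) rownames(geno$dosage)

#' Marker IDs of a genotype matrix
#' @param geno a `geno_matrix`.
#' @return character vector of marker IDs.
#' @export
marker_ids <- function(geno) colnames(geno$dosage)

# internal: subset a geno_matrix, keeping map metadata in step
subset_geno <- function(geno, lines = NULL, markers = NULL) {
  li <- if (is.null(lines)) seq_len(nrow(geno$dosage)) else lines
  mi <- if (is.null(markers)) seq_len(ncol(geno$dosage)) else markers
  geno_matrix(
    geno$dosage[li, mi, drop = FALSE],
    chrom = geno$chrom[mi],
    pos = geno$pos[mi],
    allele_freq = geno$allele_freq[mi]
  )
}

#' Pedigree table
#'
#' A pedigree records, for every line, its female and male parent and the
#' cross it came from. Lines sharing a `cross_id` (equivalently, the same
#' unordered parent pair) are full sibs. Unknown parents are `NA`.
#'
#' @param line_id character vector of line IDs (unique).
#' @param female_parent,male_parent character vectors of parent IDs; `NA`
#'   for unknown (founder) parents.
#' @param cross_id optional character vector identifying the cross; defaults
#'   to the sorted parent pair pasted together.
#'
#' @return a `data.frame` of class `pedigree` with columns `line_id`,
#'   `female_parent`, `male_parent`, `cross_id`.
#' @export
pedigree <- function(line_id, female_parent, male_parent, cross_id = NULL) {
  line_id <- as.character(line_id)
  female_parent <- as.character(female_parent)
  male_parent <- as.character(male_parent)
  if (anyDuplicated(line_id)) stop("line_id must be unique")
  n <- length(line_id)
  if (length(female_parent) != n || length(male_parent) != n)
    stop("parent vectors must match line_id length")
  if (any(line_id == female_parent | line_id == male_parent, na.rm = TRUE))
    stop("a line cannot be its own parent")
  if (is.null(cross_id)) {
    cross_id <- ifelse(
      is.na(female_parent) & is.na(male_parent), paste0("founder_", line_id),
      paste(pmin(female_parent, male_parent), pmax(female_parent, male_parent), sep = "/")
    )
  }
  out <- data.frame(
    line_id = line_id, female_parent = female_parent,
    male_parent = male_parent, cross_id = as.character(cross_id),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pedigree", "data.frame")
  out
}

# internal: coerce a plain data.frame (e.g. read from CSV) to pedigree
as_pedigree <- function(df) {
  need <- c("line_id", "female_parent", "male_parent")
  if (!all(need %in% names(df)))
    stop("pedigree needs columns line_id, female_parent, male_parent")
  pedigree(df$line_id, df$female_parent, df$male_parent,
           if ("cross_id" %in% names(df)) df$cross_id else NULL)
}
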