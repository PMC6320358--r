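#' Read / write plot-level phenotype tables
#'
#' The phenotype CSV dialect has a header row and columns `line_id`,
#' `nursery`, `environment`, `trial`, `rep`, `block`, `trait`, `date`,
#' `value` (UTF-8, missing token "NA", ISO-8601 dates). Rows whose `value`
#' does not parse as a number are dropped with a message listing their
#' line numbers.
#'
#' @param path CSV file path.
#' @return data.frame of plot records.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("line_id", "nursery", "environment", "trial", "rep", "block",
            "trait", "date", "value")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("phenotype file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  val <- suppressWarnings(as.numeric(d$value))
  bad <- which(!is.na(d$value) & d$value != "NA" & is.na(val))
  if (length(bad)) {
    message("dropped ", length(bad), " malformed row(s) at line(s): ",
            paste(utils::head(bad + 1, 10), collapse = ", "))
    d <- d[-bad, , drop = FALSE]
    val <- val[-bad]
  }
  date <- as.character(d$date)
  date[!is.na(date) & date %in% c("", "NA")] <- NA_character_
  out <- data.frame(
    line_id = d$line_id, nursery = d$nursery, environment = d$environment,
    trial = as.integer(d$trial), rep = as.integer(d$rep),
    block = as.integer(d$block), trait = d$trait,
    date = date, value = val, stringsAsFactors = FALSE
  )
  if ("is_check" %in% names(d)) out$is_check <- as.logical(d$is_check)
  out
}

#' @rdname read_phenotypes
#' @param plots plot-record data.frame.
#' @export
write_phenotypes <- function(plots, path) {
  cols <- c("line_id", "nursery", "environment", "trial", "rep", "block",
            "trait", "date", "value")
  extra <- intersect("is_check", names(plots))
  utils::write.csv(plots[, c(cols, extra)], path, row.names = FALSE,
                   na = "NA")
  invisible(path)
}

#' Read / write genotype matrices
#'
#' CSV dialect: first column `line_id`, remaining columns markers, cells
#' 0/1/2 or NA. HapMap dialect: tab-separated with the standard 11
#' metadata columns (`rs#`, `alleles`, `chrom`, `pos`, ...), diploid
#' nucleotide calls (e.g. `AA`, `AT`); calls are mapped to dosages of the
#' major allele, `NN` to missing, and non-biallelic markers are skipped
#' with a warning.
#'
#' @param path file path.
#' @param format `"csv"` or `"hapmap"`.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("csv", "hapmap")) {
  format <- match.arg(format)
  if (format == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(d)[1] != "line_id") stop("first column must be line_id")
    X <- as.matrix(d[, -1, drop = FALSE])
    storage.mode(X) <- "double"
    rownames(X) <- d$line_id
    return(geno_matrix(X))
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 12) stop("HapMap file needs 11 metadata columns plus calls")
  meta <- d[, 1:11]
  calls <- as.matrix(d[, -(1:11), drop = FALSE])
  n_mark <- nrow(d)
  lines <- colnames(calls)
  dos <- matrix(NA_real_, length(lines), n_mark,
                dimnames = list(lines, meta[[1]]))
  keep <- rep(TRUE, n_mark)
  for (m in seq_len(n_mark)) {
    cc <- calls[m, ]
    cc[cc %in% c("NN", "N", "--", "")] <- NA
    al <- unique(unlist(strsplit(stats::na.omit(cc), "")))
    if (length(al) > 2 || length(al) == 0) {
      keep[m] <- FALSE
      next
    }
    counts <- table(factor(unlist(strsplit(stats::na.omit(cc), "")), levels = al))
    major <- names(which.max(counts))
    dos[, m] <- vapply(cc, function(g) {
      if (is.na(g)) return(NA_real_)
      sum(strsplit(g, "")[[1]] == major)
    }, 0)
  }
  if (!all(keep))
    warning(sum(!keep), " non-biallelic marker(s) skipped")
  chrom <- suppressWarnings(as.integer(meta$chrom[keep]))
  geno_matrix(dos[, keep, drop = FALSE], chrom = chrom)
}

#' @rdname read_genotypes
#' @param geno a [geno_matrix()].
#' @export
write_genotypes <- function(geno, path) {
  d <- data.frame(line_id = line_ids(geno), geno$dosage,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write pedigree tables
#'
#' CSV with columns `line_id`, `female_parent`, `male_parent`, `cross_id`.
#'
#' @param path file path.
#' @return a [pedigree()].
#' @export
read_pedigree <- function(path) {
  as_pedigree(utils::read.csv(path, stringsAsFactors = FALSE,
                              colClasses = "character"))
}

#' @rdname read_pedigree
#' @param ped a [pedigree()].
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(as.data.frame(ped), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write kinship matrices
#'
#' Square CSV with line IDs as header row and first column.
#'
#' @param path file path.
#' @param kind relationship kind label ("G" or "A") attached on read.
#' @return numeric matrix.
#' @export
read_kinship <- function(path, kind = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  K <- as.matrix(d[, -1, drop = FALSE])
  rownames(K) <- d[[1]]
  storage.mode(K) <- "double"
  if (!is.null(kind)) attr(K, "kind") <- kind
  K
}

#' @rdname read_kinship
#' @param K kinship matrix with dimnames.
#' @export
write_kinship <- function(K, path) {
  d <- data.frame(line_id = rownames(K), K, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Run the full prediction pipeline on one dataset
#'
#' Executes the standard stage sequence -- BLUEs, marker QC + kinship
#' matrices, cross-validation partition, kernel predictions (G, A, G+A),
#' IBCF from GNDVI items when present -- and writes every intermediate
#' artifact plus a run log into `out_dir`.
#'
#' @param config list (or path to a YAML file) with entries: `pheno`,
#'   `geno`, `ped` (paths), `trait` (default "GY"), `environment`
#'   (optional filter), `k` (folds, default 5), `seed` (default 1),
#'   `k_spreads` (default 4), `min_H` (default 0.5), `out_dir`.
#' @return invisibly, the summary data.frame (also written to
#'   `summary.csv`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(trait = "GY", k = 5, seed = 1L, k_spreads = 4,
                   min_H = 0.5)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("pheno", "geno", "ped", "out_dir"))
    if (is.null(config[[nm]])) stop("config lacks entry: ", nm)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run_log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)
  log_line("stressgp pipeline run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  log_line("seed=%d k=%d trait=%s k_spreads=%g min_H=%g",
           config$seed, config$k, config$trait, config$k_spreads,
           config$min_H)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  plots <- stage("blues", {
    p <- read_phenotypes(config$pheno)
    if (!is.null(config$environment))
      p <- p[p$environment == config$environment, , drop = FALSE]
    filter_plot_outliers(p, config$k_spreads)
  })
  log_line("phenotypes: %d records, %d outliers removed", nrow(plots),
           attr(plots, "n_outliers"))
  blues <- stage("blues", blues_matrix(plots))
  utils::write.csv(data.frame(line_id = rownames(blues), blues,
                              check.names = FALSE),
                   file.path(config$out_dir, "blues.csv"), row.names = FALSE)

  kin <- stage("kinship", {
    geno <- read_genotypes(config$geno)
    geno <- filter_lines(filter_markers(geno))
    G <- vanraden_g(impute_mean(geno))
    ped <- read_pedigree(config$ped)
    A <- pedigree_a(ped)
    ids <- intersect(intersect(rownames(G), rownames(A)), rownames(blues))
    list(G = G[ids, ids], A = A[ids, ids], ped = ped, ids = ids)
  })
  log_line("kinship: %d lines with genotype, pedigree and phenotype",
           length(kin$ids))
  write_kinship(kin$G, file.path(config$out_dir, "G.csv"))
  write_kinship(kin$A, file.path(config$out_dir, "A.csv"))

  part <- stage("cv", kfold_partition(kin$ids, config$k, config$seed))
  write_partition(part, file.path(config$out_dir, "partition.json"))

  y <- blues[kin$ids, config$trait]
  results <- stage("predict",
                   cv_kernel_models(y, list(G = kin$G, A = kin$A), part))

  gndvi_items <- grep("^GNDVI", colnames(blues), value = TRUE)
  if (length(gndvi_items)) {
    ib <- stage("ibcf", {
      rows <- list()
      mat <- blues[kin$ids, c(config$trait, gndvi_items), drop = FALSE]
      for (f in sort(unique(part$assignments$fold))) {
        fs <- fold_sets(part, f)
        pred <- ibcf_predict_gy(mat[fs$train, , drop = FALSE],
                                mat[fs$val, gndvi_items, drop = FALSE],
                                target = config$trait)
        rows[[f]] <- data.frame(model = "IBCF", fold = f,
                                r = pearson_accuracy(y, pred))
      }
      do.call(rbind, rows)
    })
    results <- rbind(results, ib)
  }
  utils::write.csv(results, file.path(config$out_dir, "predictions.csv"),
                   row.names = FALSE)
  summary <- aggregate_grid(results, "model")
  utils::write.csv(summary, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  log_line("models: %s", paste(summary$model, collapse = ", "))
  invisible(summary)
}
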