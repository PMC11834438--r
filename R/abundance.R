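# Abundance tables are plain tibbles: first column `genus` (character),
# remaining columns one numeric vector per sample. Presence tables share the
# shape with all values in {0, 1}. Matrix views are genera x samples.

#' Convert an abundance tibble to a genera-by-samples matrix
#'
#' Validates the table on the way: the first column must hold unique genus
#' labels, the remaining columns must be numeric, non-negative and uniquely
#' named.
#'
#' @param table A tibble with a `genus` identifier column followed by one
#'   numeric column per sample.
#' @param allow_negative Permit negative values (used for clr-transformed
#'   tables, which are log-ratios rather than abundances).
#' @return A numeric matrix with genus row names and sample column names.
#' @export
as_abundance_matrix <- function(table, allow_negative = FALSE) {
  if (!is.data.frame(table) || ncol(table) < 2L) {
    abort("`table` must be a data frame with a genus column and at least one sample column.")
  }
  genus <- as.character(table[[1L]])
  if (anyNA(genus) || any(!nzchar(genus))) {
    abort("Genus identifiers must be non-missing, non-empty strings.")
  }
  if (anyDuplicated(genus)) {
    dup <- unique(genus[duplicated(genus)])
    abort(paste0("Duplicate genus identifiers: ", toString(head(dup, 5L)), "."))
  }
  samples <- names(table)[-1L]
  if (anyDuplicated(samples)) {
    dup <- unique(samples[duplicated(samples)])
    abort(paste0("Duplicate sample identifiers: ", toString(head(dup, 5L)), "."))
  }
  body <- table[-1L]
  bad_col <- which(!vapply(body, is.numeric, logical(1L)))
  if (length(bad_col)) {
    abort(paste0("Non-numeric sample column: ", samples[bad_col[1L]], "."))
  }
  values <- as.matrix(body)
  dimnames(values) <- list(genus, samples)
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    abort(paste0("Missing value at genus '", genus[idx[1L]], "', sample '", samples[idx[2L]], "'."))
  }
  if (!allow_negative && any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1L, ]
    abort(paste0("Negative value at genus '", genus[idx[1L]], "', sample '", samples[idx[2L]], "'."))
  }
  values
}

matrix_to_table <- function(values) {
  out <- tibble::as_tibble(values, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(genus = rownames(values)), out)
}

#' Read a genus-by-sample abundance table from delimited text
#'
#' @param path Path to a TSV/CSV file whose header row holds sample
#'   identifiers and whose first column holds genus labels (or the transpose,
#'   see `genera_as_rows`).
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`.csv` comma, otherwise tab).
#' @param genera_as_rows Set to `FALSE` for files with samples as rows and
#'   genera as columns; the table is transposed to the genera-as-rows layout.
#' @return A validated abundance tibble (`genus` column + sample columns).
#' @export
read_abundance_table <- function(path, delim = NULL, genera_as_rows = TRUE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, na = c("NA", ""))
  prob <- readr::problems(raw)
  if (nrow(prob)) {
    abort(paste0(
      "Non-numeric cell at file row ", prob$row[1L], ", column ", prob$col[1L],
      " (saw '", prob$actual[1L], "')."
    ))
  }
  names(raw)[1L] <- "genus"
  if (!genera_as_rows) {
    values <- t(as_transposed_matrix(raw))
    raw <- matrix_to_table(values)
  }
  as_abundance_matrix(raw) # validation side effects
  raw
}

# samples-as-rows variant: first column holds sample ids, header holds genera
as_transposed_matrix <- function(table) {
  m <- suppressWarnings(as.matrix(table[-1L]))
  storage.mode(m) <- "double"
  rownames(m) <- as.character(table[[1L]])
  m
}

#' Write an abundance tibble as delimited text
#'
#' @inheritParams as_abundance_matrix
#' @param path Output file path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path, delim = "\t") {
  as_abundance_matrix(table)
  readr::write_delim(table, path, delim = delim)
  invisible(path)
}

#' Binarise an abundance table into detection calls
#'
#' A genus is detected in a sample when its abundance exceeds
#' `detection_threshold`; abundance is otherwise ignored, which is what makes
#' the co-detection model robust to compositional scaling.
#'
#' @inheritParams as_abundance_matrix
#' @param detection_threshold Non-negative abundance cutoff; values strictly
#'   greater count as detected. Default 0 (any non-zero abundance).
#' @return A presence tibble of the same shape with values in {0, 1}.
#' @export
to_presence <- function(table, detection_threshold = 0) {
  if (detection_threshold < 0) abort("`detection_threshold` must be >= 0.")
  values <- as_abundance_matrix(table)
  matrix_to_table((values > detection_threshold) * 1)
}

#' Per-genus prevalence
#'
#' Prevalence \eqn{p_i} is the fraction of samples in which genus *i* is
#' detected.
#'
#' @inheritParams to_presence
#' @return A tibble with columns `genus` and `prevalence`.
#' @export
prevalence <- function(table, detection_threshold = 0) {
  values <- as_abundance_matrix(table)
  if (ncol(values) < 1L) abort("Prevalence needs at least one sample.")
  tibble::tibble(
    genus = rownames(values),
    prevalence = unname(rowMeans(values > detection_threshold))
  )
}

#' Drop rare genera by prevalence
#'
#' Removes genera detected in less than `min_prev` of samples; genera at
#' exactly the threshold are retained. The sample set is unchanged.
#'
#' @inheritParams to_presence
#' @param min_prev Minimum prevalence in \[0, 1\]; default 0.10.
#' @param companion Optional second table (e.g. the raw counts paired with a
#'   presence table) subset to the same retained genera; when supplied a list
#'   with elements `table` and `companion` is returned.
#' @return The filtered tibble, or a list of two when `companion` is given.
#' @export
filter_by_prevalence <- function(table, min_prev = 0.10, detection_threshold = 0,
                                 companion = NULL) {
  if (min_prev < 0 || min_prev > 1) abort("`min_prev` must be in [0, 1].")
  prev <- prevalence(table, detection_threshold)
  keep <- prev$genus[prev$prevalence >= min_prev]
  if (!length(keep)) {
    abort(paste0(
      "All genera fall below prevalence ", min_prev,
      "; review the threshold or the detection cutoff."
    ))
  }
  out <- dplyr::filter(table, .data$genus %in% keep)
  if (is.null(companion)) return(out)
  list(table = out, companion = dplyr::filter(companion, .data$genus %in% keep))
}

looks_like_counts <- function(values) {
  all(values == round(values))
}

#' Centered log-ratio transform
#'
#' Per sample column, `clr(x)_i = log(x_i) - mean_j log(x_j)` after zero
#' replacement, so each transformed column sums to zero. Used to lift
#' compositional closure before Pearson correlation.
#'
#' @inheritParams as_abundance_matrix
#' @param zero_policy `"auto"` picks `"pseudocount"` for integer tables and
#'   `"half_min"` for relative abundances. `"pseudocount"` adds `pseudocount`
#'   to every cell; `"half_min"` replaces zeros with half the smallest
#'   non-zero value in the table and re-closes each column; `"none"` requires
#'   strictly positive input.
#' @param pseudocount Value added under the `"pseudocount"` policy.
#' @return A tibble of clr values with the input's shape.
#' @export
clr_transform <- function(table, zero_policy = c("auto", "pseudocount", "half_min", "none"),
                          pseudocount = 1) {
  zero_policy <- match.arg(zero_policy)
  values <- as_abundance_matrix(table)
  zero_cols <- colSums(values) == 0
  if (any(zero_cols)) {
    abort(paste0("Sample column(s) with all-zero abundance: ",
                 toString(head(colnames(values)[zero_cols], 5L)), "."))
  }
  if (zero_policy == "auto") {
    zero_policy <- if (looks_like_counts(values)) "pseudocount" else "half_min"
  }
  pos <- switch(zero_policy,
    pseudocount = values + pseudocount,
    half_min = {
      repl <- min(values[values > 0]) / 2
      v <- values
      v[v == 0] <- repl
      sweep(v, 2L, colSums(v), `/`)
    },
    none = {
      if (any(values == 0)) abort("Zeros present but `zero_policy = \"none\"`.")
      values
    }
  )
  lv <- log(pos)
  matrix_to_table(sweep(lv, 2L, colMeans(lv), `-`))
}
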