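#' Canonical feature naming
#'
#' The model consumes a 23-dimensional feature vector per TLC measurement:
#' five mobile-phase volume fractions, sixteen functional-group counts, the
#' benzene-ring count and the dipole moment.
#'
#' @return `fg_count_names()`: the 16 count columns in canonical order.
#'   `tlc_feature_names()`: the 23 model features, ordered
#'   solvent (5) | counts (16) | NBen | DM.  `tlc_csv_columns()`: the
#'   canonical CSV header (note NBen and DM precede the counts there).
#' @export
fg_count_names <- function() {
  c("CtPh", "CtOH", "CtAl", "CtCO2H", "CtRCO2R", "CtR2CO", "CtROR", "CtCN",
    "CtNH2", "CtNO2", "CtAm", "CtMe", "CtF", "CtCl", "CtBr", "CtI")
}

#' @rdname fg_count_names
#' @export
solvent_names <- function() c("Hex", "EA", "DCM", "MeOH", "Et2O")

#' @rdname fg_count_names
#' @export
tlc_feature_names <- function() {
  c(solvent_names(), fg_count_names(), "NBen", "DM")
}

#' @rdname fg_count_names
#' @export
tlc_csv_columns <- function() {
  c("id", solvent_names(), "NBen", "DM", fg_count_names(), "Rf")
}

#' Mobile-phase composition
#'
#' Validates a binary (or general) mixture of the five eluent solvents.
#' Fractions must lie in \[0, 1\] and sum to one within 1e-6; with
#' `normalize = TRUE` a non-unit sum is rescaled instead of rejected.
#'
#' @param hex,ea,dcm,meoh,et2o volume fractions.
#' @param normalize rescale fractions to sum to one instead of rejecting.
#' @return named numeric vector of length 5.
#' @export
solvent_composition <- function(hex = 0, ea = 0, dcm = 0, meoh = 0,
                                et2o = 0, normalize = FALSE) {
  v <- c(Hex = hex, EA = ea, DCM = dcm, MeOH = meoh, Et2O = et2o)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    stop("solvent fractions must be finite and in [0, 1]")
  }
  s <- sum(v)
  if (abs(s - 1) > 1e-6) {
    if (!normalize) {
      stop(sprintf("solvent fractions sum to %.6g, not 1", s))
    }
    if (s <= 0) stop("cannot normalize an all-zero composition")
    v <- v / s
  }
  v
}

#' Functional-group count vector
#'
#' @param ... counts named by the canonical abbreviations (see
#'   [fg_count_names()]); omitted groups default to 0.  Alternatively a
#'   single named numeric vector.
#' @return named integer vector of length 16 in canonical order.
#' @export
fg_counts <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    args <- as.list(args[[1]])
  }
  nm <- fg_count_names()
  unknown <- setdiff(names(args), nm)
  if (length(unknown)) {
    stop("unknown functional-group column(s): ", paste(unknown, collapse = ", "))
  }
  v <- stats::setNames(integer(16), nm)
  for (g in names(args)) v[[g]] <- args[[g]]
  if (any(v < 0) || any(v != round(v))) {
    stop("functional-group counts must be non-negative integers")
  }
  storage.mode(v) <- "integer"
  v
}

#' A single TLC measurement record
#'
#' @param solvent a [solvent_composition()].
#' @param fg a [fg_counts()] vector.
#' @param n_ben benzene-ring count (non-negative integer).
#' @param dm dipole moment in Debye (non-negative).
#' @param rf observed retardation factor in \[0, 1\], or `NA` for
#'   prediction-only records.
#' @param id opaque record label.
#' @return list of class `tlc_record`.
#' @export
tlc_record <- function(solvent, fg = fg_counts(), n_ben = 0, dm = 0,
                       rf = NA_real_, id = "r1") {
  stopifnot(length(solvent) == 5L, length(fg) == 16L)
  if (n_ben < 0 || n_ben != round(n_ben)) stop("n_ben must be a non-negative integer")
  if (!is.finite(dm) || dm < 0) stop("dm must be a non-negative real")
  if (!is.na(rf) && (rf < 0 || rf > 1)) stop("rf must lie in [0, 1]")
  structure(list(solvent = solvent, fg = fg, n_ben = n_ben, dm = dm,
                 rf = rf, id = id),
            class = "tlc_record")
}

#' Assemble the 23-dimensional model feature vector
#'
#' Concatenates \[solvent (5) | counts (16) | NBen | DM\] in the canonical
#' model order.  Accepts a single [tlc_record()] or a dataset data.frame
#' carrying the canonical columns; round-trips losslessly through the CSV
#' schema.
#'
#' @param x a `tlc_record` or data.frame.
#' @return named numeric vector (single record) or matrix (dataset).
#' @export
assemble_features <- function(x) {
  fn <- tlc_feature_names()
  if (inherits(x, "tlc_record")) {
    return(stats::setNames(
      c(unname(x$solvent), unname(x$fg), x$n_ben, x$dm), fn))
  }
  x <- as.data.frame(x)
  missing <- setdiff(fn, colnames(x))
  if (length(missing)) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(x[, fn, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  m
}

validate_tlc_frame <- function(df, solvent_mode = c("strict", "normalize"),
                               what = "dataset") {
  solvent_mode <- match.arg(solvent_mode)
  sn <- solvent_names()
  fgn <- fg_count_names()
  bad_row <- function(test, msg) {
    rows <- which(test)
    if (length(rows)) {
      stop(sprintf("%s: %s in row(s) %s", what, msg,
                   paste(utils::head(rows, 10), collapse = ", ")))
    }
  }
  num_cols <- c(sn, "NBen", "DM", fgn)
  for (cc in num_cols) {
    if (!is.numeric(df[[cc]])) stop(what, ": column ", cc, " is not numeric")
  }
  sums <- rowSums(df[, sn, drop = FALSE])
  off <- abs(sums - 1) > 1e-6
  if (any(off)) {
    if (solvent_mode == "strict") {
      bad_row(off, "solvent fractions do not sum to 1")
    } else {
      df[off, sn] <- df[off, sn, drop = FALSE] / sums[off]
      warning(sprintf("%s: renormalized solvent fractions in %d row(s)",
                      what, sum(off)))
    }
  }
  bad_row(apply(df[, sn, drop = FALSE], 1, function(v) any(v < 0 | v > 1)),
          "solvent fraction outside [0, 1]")
  cnt <- as.matrix(df[, c(fgn, "NBen"), drop = FALSE])
  bad_row(apply(cnt, 1, function(v) any(v < 0 | v != round(v))),
          "count column not a non-negative integer")
  bad_row(df$DM < 0, "negative dipole moment")
  if ("Rf" %in% colnames(df)) {
    bad_row(!is.na(df$Rf) & (df$Rf < 0 | df$Rf > 1), "Rf outside [0, 1]")
  }
  df
}

#' Read a TLC dataset from the canonical CSV schema
#'
#' Expects the header `id,Hex,EA,DCM,MeOH,Et2O,NBen,DM,CtPh,...,CtI,Rf`
#' (`Rf` optional for prediction-only tables).  Rows violating the schema
#' invariants are rejected with row-numbered diagnostics; compositions not
#' summing to one are rejected in `"strict"` mode and rescaled (with a
#' warning) in `"normalize"` mode.
#'
#' @param path CSV file path.
#' @param solvent_mode `"strict"` (default) or `"normalize"`.
#' @return data.frame of class `tlc_dataset` in canonical column order.
#' @export
read_tlc_dataset <- function(path, solvent_mode = c("strict", "normalize")) {
  solvent_mode <- match.arg(solvent_mode)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  expected <- tlc_csv_columns()
  unknown <- setdiff(colnames(df), expected)
  if (length(unknown)) {
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(setdiff(expected, "Rf"), colnames(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  df <- validate_tlc_frame(df, solvent_mode, what = basename(path))
  df <- df[, intersect(expected, colnames(df)), drop = FALSE]
  class(df) <- c("tlc_dataset", "data.frame")
  df
}

#' Write a TLC dataset in the canonical CSV schema
#'
#' @param x data.frame with the canonical columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tlc_dataset <- function(x, path) {
  cols <- intersect(tlc_csv_columns(), colnames(x))
  utils::write.csv(as.data.frame(x)[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a TLC dataset data.frame from parts
#'
#' @param solvent data.frame/matrix with the five solvent columns.
#' @param fg matrix/data.frame with the 16 count columns.
#' @param n_ben,dm numeric vectors.
#' @param rf observed Rf (or `NA`).
#' @param id record labels (default `s1..sn`).
#' @return data.frame of class `tlc_dataset`.
#' @export
tlc_dataset <- function(solvent, fg, n_ben, dm, rf = NA_real_, id = NULL) {
  n <- nrow(as.data.frame(solvent))
  if (is.null(id)) id <- sprintf("s%d", seq_len(n))
  df <- data.frame(id = id, as.data.frame(solvent)[, solvent_names()],
                   NBen = n_ben, DM = dm,
                   as.data.frame(fg)[, fg_count_names()],
                   Rf = rf, check.names = FALSE)
  df <- validate_tlc_frame(df, "strict")
  rownames(df) <- NULL
  class(df) <- c("tlc_dataset", "data.frame")
  df
}
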