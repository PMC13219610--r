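## Core tabular types: descriptor specifications, compound tables, prediction
## sets, plus the CSV/JSON plumbing every other module consumes.

#' Create a descriptor specification
#'
#' Per-descriptor metadata: measurement kind, bounds, distributional moments
#' used by the synthetic generator, and the monotone direction the descriptor
#' is constrained to (+1 non-decreasing, -1 non-increasing, 0 unconstrained).
#'
#' @param name descriptor name.
#' @param kind `"discrete"` or `"continuous"`.
#' @param lower,upper bounds in descriptor units (integers when discrete).
#' @param mode_or_median mode (discrete) or median (continuous).
#' @param mean,sd marginal mean and standard deviation.
#' @param variance marginal variance; defaults to `sd^2`.
#' @param kurtosis Fisher excess kurtosis (normal = 0) unless stated otherwise.
#' @param monotone_direction one of `-1`, `0`, `+1`.
#' @return an object of class `descriptor_spec`.
#' @export
descriptor_spec <- function(name, kind = c("continuous", "discrete"),
                            lower, upper, mode_or_median = NA_real_,
                            mean = NA_real_, sd = NA_real_,
                            variance = if (is.na(sd)) NA_real_ else sd^2,
                            kurtosis = NA_real_, monotone_direction = 0L) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!monotone_direction %in% c(-1L, 0L, 1L))
    stop_tox("monotone_direction must be -1, 0 or +1 for '%s'", name)
  if (lower > upper)
    stop_tox("descriptor '%s': lower (%g) > upper (%g)", name, lower, upper)
  if (!is.na(mode_or_median) &&
      (mode_or_median < lower || mode_or_median > upper))
    stop_tox("descriptor '%s': mode/median outside [lower, upper]", name)
  if (!is.na(sd) && sd < 0) stop_tox("descriptor '%s': sd < 0", name)
  if (!is.na(sd) && !is.na(variance) &&
      abs(variance - sd^2) > 0.01 * max(1, variance))
    stop_tox("descriptor '%s': variance (%g) inconsistent with sd^2 (%g)",
             name, variance, sd^2)
  if (kind == "discrete" &&
      (lower != round(lower) || upper != round(upper)))
    stop_tox("descriptor '%s': discrete bounds must be integers", name)
  structure(list(name = name, kind = kind, lower = lower, upper = upper,
                 mode_or_median = mode_or_median, mean = mean, sd = sd,
                 variance = variance, kurtosis = kurtosis,
                 monotone_direction = as.integer(monotone_direction)),
            class = "descriptor_spec")
}

#' Default descriptor specifications for the eight-descriptor pIGC50 model
#'
#' Encodes the published marginal summaries of the curated 1792-compound
#' Tetrahymena pyriformis set: bounds, mode (discrete) or median (continuous),
#' mean, SD, variance and kurtosis per descriptor, plus the target pIGC50.
#' Monotone directions default to +1 for LogP, MW and nDB and -1 for nROH;
#' all other descriptors are unconstrained.  For the three discrete counts
#' only bounds and modes are published; their mean/SD fields carry the moments
#' implied by the generator's bounded binomial family (see
#' [generator_config()]), not printed values.
#'
#' @param include_target also append a spec for the `pIGC50` target.
#' @return list of [descriptor_spec()] objects.
#' @export
descriptor_specs <- function(include_target = FALSE) {
  binom_m <- function(l, u, p) l + (u - l) * p
  binom_s <- function(l, u, p) sqrt((u - l) * p * (1 - p))
  specs <- list(
    descriptor_spec("MW", "continuous", 0, 488.59, 146.1, 150.88, 49.971,
                    2497.1, 3.873, +1L),
    descriptor_spec("A", "continuous", 0, 1.630, 0.001, 0.222, 0.284,
                    0.080, 1.796, 0L),
    descriptor_spec("LogP", "continuous", -2.585, 7.206, 1.976, 1.981, 1.291,
                    1.666, 0.243, +1L),
    descriptor_spec("GATS1p", "continuous", 0.201, 2.5, 1.043, 1.084, 0.391,
                    0.153, -0.757, 0L),
    descriptor_spec("B", "continuous", 0, 2.102, 0.427, 0.462, 0.229,
                    0.052, 4.834, 0L),
    descriptor_spec("NRB", "discrete", 0, 15, 1,
                    binom_m(0, 15, 0.09375), binom_s(0, 15, 0.09375),
                    kurtosis = NA_real_, monotone_direction = 0L),
    descriptor_spec("nROH", "discrete", 0, 3, 0,
                    binom_m(0, 3, 0.10), binom_s(0, 3, 0.10),
                    kurtosis = NA_real_, monotone_direction = -1L),
    descriptor_spec("nDB", "discrete", 0, 6, 0,
                    binom_m(0, 6, 0.10), binom_s(0, 6, 0.10),
                    kurtosis = NA_real_, monotone_direction = +1L)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  if (include_target) {
    specs$pIGC50 <- descriptor_spec("pIGC50", "continuous", 0.334, 6.36, 3.25,
                                    3.267, 1.051, 1.104, -0.275, 0L)
  }
  specs
}

#' Named vector of monotone-constraint directions
#'
#' @param specs list of descriptor specs.
#' @return integer vector (one entry per descriptor) with values in
#'   `c(-1, 0, 1)`.
#' @export
constraint_map <- function(specs = descriptor_specs()) {
  vapply(specs, function(s) s$monotone_direction, integer(1))
}

infer_spec <- function(name, x) {
  if (!length(x))
    return(descriptor_spec(name, "continuous", -Inf, Inf,
                           monotone_direction = switch(name, LogP = , MW = ,
                                                       nDB = 1L, nROH = -1L,
                                                       0L)))
  is_int <- all(x == round(x))
  descriptor_spec(
    name, if (is_int) "discrete" else "continuous",
    lower = min(x), upper = max(x),
    mode_or_median = stats::median(x),
    mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
    kurtosis = if (length(x) > 3) sample_kurtosis(x) else NA_real_,
    monotone_direction = switch(name, LogP = , MW = , nDB = 1L,
                                nROH = -1L, 0L))
}

#' Construct a compound table
#'
#' The universal tabular currency: unique compound ids, an n x p numeric
#' descriptor matrix, an optional pIGC50 target vector, and per-column
#' descriptor specs.
#'
#' @param ids character vector of unique compound identifiers.
#' @param X numeric matrix (rows = compounds, named columns = descriptors).
#' @param y optional numeric pIGC50 vector.
#' @param specs optional list of [descriptor_spec()]s aligned to columns;
#'   inferred from the data when omitted.
#' @return object of class `compound_table`.
#' @export
compound_table <- function(ids, X, y = NULL, specs = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_tox("duplicate compound ids are not allowed")
  if (length(ids) != nrow(X)) stop_tox("length(ids) != nrow(X)")
  if (is.null(colnames(X))) stop_tox("descriptor matrix must have column names")
  if (nrow(X) > 0 && anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop_tox("missing value at row %d, column %s", bad[1],
             colnames(X)[bad[2]])
  }
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != nrow(X)) stop_tox("length(y) != nrow(X)")
    if (anyNA(y)) stop_tox("missing values in target")
  }
  if (is.null(specs)) {
    specs <- lapply(colnames(X), function(nm) infer_spec(nm, X[, nm]))
    names(specs) <- colnames(X)
  }
  if (length(specs) != ncol(X))
    stop_tox("specs length (%d) != number of descriptor columns (%d)",
             length(specs), ncol(X))
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    if (sp$kind == "discrete" && nrow(X) > 0) {
      xj <- X[, j]
      if (any(xj != round(xj)))
        stop_tox("discrete column %s contains non-integers", sp$name)
      if (any(xj < sp$lower | xj > sp$upper))
        stop_tox("discrete column %s outside [%g, %g]", sp$name,
                 sp$lower, sp$upper)
    }
  }
  structure(list(ids = ids, X = X, y = y, specs = specs),
            class = "compound_table")
}

#' @export
print.compound_table <- function(x, ...) {
  cat(sprintf("<compound_table> %d compounds x %d descriptors%s\n",
              nrow(x$X), ncol(x$X),
              if (is.null(x$y)) "" else " (+ pIGC50 target)"))
  cat("  descriptors:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.compound_table <- function(x) dim(x$X)

#' Subset a compound table by row indices
#'
#' @param table a [compound_table()].
#' @param idx integer row indices.
#' @return the subsetted `compound_table`.
#' @export
table_subset <- function(table, idx) {
  compound_table(table$ids[idx], table$X[idx, , drop = FALSE],
                 if (is.null(table$y)) NULL else table$y[idx], table$specs)
}

#' Read a compound table from CSV
#'
#' Expects a header row, a leading `compound_id` column and numeric descriptor
#' columns.  Rows that duplicate an id with identical values are collapsed to
#' the first occurrence (the count is reported via `attr(, "dedup_count")` and
#' a message); duplicated ids with conflicting values are an error, mirroring
#' structure-based deduplication done upstream of descriptor calculation.
#'
#' @param path CSV file path.
#' @param target_column name of the target column if present (default
#'   `"pIGC50"`; use `NULL` to force descriptor-only reading).
#' @param specs optional descriptor specs; inferred when omitted.
#' @return a [compound_table()] with attribute `dedup_count`.
#' @export
read_compound_table <- function(path, target_column = "pIGC50", specs = NULL) {
  if (!file.exists(path)) stop_tox("file not found: %s", path)
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop_tox("expected compound_id plus descriptor columns")
  if (names(df)[1] != "compound_id")
    stop_tox("first column must be 'compound_id' (got '%s')", names(df)[1])
  num_cols <- setdiff(names(df), "compound_id")
  mat <- matrix(NA_real_, nrow(df), length(num_cols),
                dimnames = list(NULL, num_cols))
  for (nm in num_cols) {
    raw <- trimws(df[[nm]])
    bad <- which(raw == "" | is.na(raw))
    if (length(bad))
      stop_tox("missing value at row %d, column %s", bad[1], nm)
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v))
    if (length(bad))
      stop_tox("non-numeric value '%s' at row %d, column %s",
               raw[bad[1]], bad[1], nm)
    mat[, nm] <- v
  }
  ids <- df$compound_id
  dedup_count <- 0L
  if (anyDuplicated(ids)) {
    keep <- !duplicated(ids)
    for (id in unique(ids[duplicated(ids)])) {
      rows <- mat[ids == id, , drop = FALSE]
      if (any(abs(sweep(rows, 2, rows[1, ])) > 1e-9))
        stop_tox("duplicate id '%s' has conflicting descriptor values", id)
    }
    dedup_count <- sum(!keep)
    message(sprintf("read_compound_table: collapsed %d duplicated id row(s)",
                    dedup_count))
    mat <- mat[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  y <- NULL
  if (!is.null(target_column) && target_column %in% colnames(mat)) {
    y <- mat[, target_column]
    mat <- mat[, setdiff(colnames(mat), target_column), drop = FALSE]
  }
  out <- compound_table(ids, mat, y, specs)
  attr(out, "dedup_count") <- dedup_count
  out
}

#' Write a compound table to CSV
#'
#' Single fixed dialect: comma separator, `.` decimal, UTF-8, mandatory
#' header, leading `compound_id` column.  Values survive a round trip through
#' [read_compound_table()] to at least 12 significant digits.
#'
#' @param table a [compound_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(table, path) {
  stopifnot(inherits(table, "compound_table"))
  df <- data.frame(compound_id = table$ids, stringsAsFactors = FALSE)
  for (nm in colnames(table$X))
    df[[nm]] <- formatC(table$X[, nm], digits = 15, format = "g")
  if (!is.null(table$y))
    df[["pIGC50"]] <- formatC(table$y, digits = 15, format = "g")
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_tox("cannot write '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' Per-column distributional summary of a compound table
#'
#' One record per descriptor column (plus the target when present) with min,
#' max, mean, SD, variance, median and sample-corrected Fisher excess
#' kurtosis, mirroring the published descriptor summary table.
#'
#' @param table a [compound_table()] with at least 2 rows.
#' @return data.frame with one row per column.
#' @export
summarize_table <- function(table) {
  stopifnot(inherits(table, "compound_table"))
  if (nrow(table$X) < 2) stop_tox("summarize_table requires n >= 2")
  cols <- as.data.frame(table$X)
  if (!is.null(table$y)) cols$pIGC50 <- table$y
  recs <- lapply(names(cols), function(nm) {
    x <- cols[[nm]]
    data.frame(variable = nm, min = min(x), max = max(x), mean = mean(x),
               sd = sd(x), variance = var(x), median = median(x),
               kurtosis = sample_kurtosis(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Construct a prediction set
#'
#' Container holding observed values, point predictions and (optionally)
#' central interval bounds and predictive SDs; the currency of every
#' evaluation metric.
#'
#' @param y observed values.
#' @param y_hat predicted values.
#' @param lower,upper optional interval bounds (must bracket `y_hat`).
#' @param sigma optional non-negative predictive SDs.
#' @return object of class `prediction_set`.
#' @export
prediction_set <- function(y, y_hat, lower = NULL, upper = NULL, sigma = NULL) {
  n <- length(y)
  if (length(y_hat) != n) stop_tox("y and y_hat length mismatch")
  chk <- function(v, nm) {
    if (!is.null(v) && length(v) != n) stop_tox("%s length mismatch", nm)
    v
  }
  lower <- chk(lower, "lower"); upper <- chk(upper, "upper")
  sigma <- chk(sigma, "sigma")
  if (!is.null(lower) && !is.null(upper)) {
    if (any(lower > y_hat + 1e-12) || any(upper < y_hat - 1e-12))
      stop_tox("intervals must satisfy lower <= y_hat <= upper")
  }
  if (!is.null(sigma) && any(sigma < 0)) stop_tox("sigma must be >= 0")
  structure(list(y = as.numeric(y), y_hat = as.numeric(y_hat),
                 lower = lower, upper = upper, sigma = sigma),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> N = %d%s%s\n", length(x$y),
              if (is.null(x$lower)) "" else ", with intervals",
              if (is.null(x$sigma)) "" else ", with sigma"))
  invisible(x)
}
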