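# Readers/writers for the canonical on-disk forms. The canonical CT table is
# long (tidy) tab-delimited so that plate and duplicate annotation travel
# without multi-index headers; a wide assays-x-samples dialect is accepted
# for convenience and converted on read.

.UNDET_STRINGS <- c("Undetermined", "undetermined", "UNDETERMINED", "NA", "")

.parseCt <- function(x, where = "ct") {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  det <- !(x %in% .UNDET_STRINGS)
  val <- suppressWarnings(as.numeric(x[det]))
  if (anyNA(val)) {
    bad <- which(det)[is.na(val)]
    stop(sprintf("non-numeric %s value '%s' at row %d", where,
                 x[bad[1]], bad[1]), call. = FALSE)
  }
  out[det] <- val
  out
}

.requireCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

.validateCtLong <- function(ct, maxCycle = 40) {
  .requireCols(ct, c("assay_id", "mirna_name", "plate", "sample_id", "ct"),
               "CT table")
  if (!"duplicate_group" %in% names(ct)) ct$duplicate_group <- ""
  ct$duplicate_group[is.na(ct$duplicate_group)] <- ""
  for (col in c("assay_id", "mirna_name", "plate", "sample_id",
                "duplicate_group"))
    ct[[col]] <- as.character(ct[[col]])
  if (!is.numeric(ct$ct)) ct$ct <- .parseCt(ct$ct)
  bad <- which(!is.na(ct$ct) & (ct$ct < 0 | ct$ct > maxCycle))
  if (length(bad))
    stop(sprintf("ct value %g outside [0, %g] at row %d",
                 ct$ct[bad[1]], maxCycle, bad[1]), call. = FALSE)
  if (!all(ct$plate %in% c("A", "B")))
    stop("plate must be 'A' or 'B'", call. = FALSE)
  key <- paste(ct$assay_id, ct$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop(sprintf("duplicated (assay_id, sample_id) pair: (%s)",
                 gsub("\r", ", ", d)), call. = FALSE)
  }
  ct
}

.validateSampleSheet <- function(samples) {
  .requireCols(samples, c("sample_id", "group"), "sample sheet")
  samples$sample_id <- as.character(samples$sample_id)
  samples$group <- as.character(samples$group)
  allowed <- c("knockdown", "control")
  bad <- setdiff(unique(samples$group), allowed)
  if (length(bad))
    stop(sprintf("unknown group label(s): %s (allowed: %s)",
                 paste(bad, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  for (g in allowed)
    if (!any(samples$group == g))
      stop("empty group: ", g, call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id: ",
         samples$sample_id[duplicated(samples$sample_id)][1], call. = FALSE)
  if (!"label" %in% names(samples)) samples$label <- samples$sample_id
  samples$label <- as.character(samples$label)
  samples[, c("sample_id", "group", "label")]
}

#' Read a CT table export
#'
#' Reads tab-delimited threshold-cycle exports of TaqMan-style array cards.
#' The long dialect has columns `assay_id`, `mirna_name`, `plate`,
#' `sample_id`, `ct`, `duplicate_group`; the wide dialect has one row per
#' assay (`assay_id`, `mirna_name`, `plate`, `duplicate_group`, then one CT
#' column per sample) and is converted to long form on read. The strings
#' `"Undetermined"`, `"undetermined"`, `"NA"` and empty cells map to the
#' undetermined sentinel (`NA`); all other values must parse as cycles in
#' `[0, maxCycle]`. Parsing uses the decimal point only (locale-independent).
#'
#' @param path file path
#' @param dialect `"long"` (default, canonical) or `"wide"`
#' @param maxCycle maximum instrument cycle (default 40)
#' @return data.frame in long form with numeric `ct` (`NA` = undetermined)
#' @seealso [writeCtTable()], [CtExperiment()]
#' @export
readCtTable <- function(path, dialect = c("long", "wide"), maxCycle = 40) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  if (dialect == "wide") {
    .requireCols(df, c("assay_id", "mirna_name", "plate"), "CT table (wide)")
    if (!"duplicate_group" %in% names(df)) df$duplicate_group <- ""
    idcols <- c("assay_id", "mirna_name", "plate", "duplicate_group")
    scols <- setdiff(names(df), idcols)
    if (!length(scols))
      stop("CT table (wide): no sample columns found", call. = FALSE)
    df <- do.call(rbind, lapply(scols, function(s)
      data.frame(df[idcols], sample_id = s, ct = df[[s]],
                 stringsAsFactors = FALSE)))
    df <- df[, c("assay_id", "mirna_name", "plate", "sample_id", "ct",
                 "duplicate_group")]
  }
  .validateCtLong(df, maxCycle = maxCycle)
}

#' Write a CT table in the canonical long form
#'
#' Cycle values are written as fixed-precision decimal text (`digits` decimal
#' places) and undetermined cells as `"Undetermined"`, so a write/read
#' round-trip reproduces records exactly.
#'
#' @param ct long CT data.frame (as from [readCtTable()]) or a
#'   [CtExperiment-class]
#' @param path output path
#' @param digits decimal places for cycle values (default 4)
#' @return `path`, invisibly
#' @export
writeCtTable <- function(ct, path, digits = 4) {
  if (is(ct, "CtExperiment")) ct <- .ctLongFromExperiment(ct)
  ct <- .validateCtLong(ct)
  out <- ct
  out$ct <- ifelse(is.na(ct$ct), "Undetermined",
                   formatC(ct$ct, format = "f", digits = digits))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.ctLongFromExperiment <- function(x) {
  m <- ctValues(x)
  data.frame(
    assay_id = rep(rownames(m), times = ncol(m)),
    mirna_name = rep(unname(mirnaNames(x)), times = ncol(m)),
    plate = rep(unname(plates(x)), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    ct = as.vector(m),
    duplicate_group = rep(unname(duplicateGroups(x)), times = ncol(m)),
    stringsAsFactors = FALSE)
}

#' Read a sample sheet
#'
#' Tab-delimited file with columns `sample_id`, `group` and optionally
#' `label` (e.g. the siRNA identity). Groups are restricted to
#' `"knockdown"` and `"control"`; both must be non-empty. File order is
#' preserved.
#'
#' @param path file path
#' @return data.frame with columns `sample_id`, `group`, `label`
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  .validateSampleSheet(df)
}

#' Write a sample sheet
#' @param samples sample sheet data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSampleSheet <- function(samples, path) {
  samples <- .validateSampleSheet(samples)
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
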