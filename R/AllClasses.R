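#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData
NULL

#' CtExperiment: threshold-cycle matrix with plate and duplicate annotation
#'
#' `CtExperiment` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds one assay, `"ct"`: raw qPCR threshold cycles per (assay, sample).
#' Non-detected wells (the instrument's "Undetermined" call) are stored as
#' `NA` -- a distinct sentinel, never a substitute numeric cycle -- so that
#' downstream rules can distinguish "not detected" from "detected late".
#'
#' Row metadata carries `mirna_name`, `plate` (`"A"` or `"B"`) and
#' `duplicate_group` (non-empty for assays measured in duplicate; all members
#' of a group must name the same miRNA). Column metadata carries the sample
#' `group` (`"knockdown"` or `"control"`) and a free-text `label`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]; no extra slots.
#' @seealso [CtExperiment()] the constructor, [readCtTable()],
#'   [readSampleSheet()]
#' @export
setClass("CtExperiment", contains = "SummarizedExperiment")

.validCtExperiment <- function(object) {
  msg <- character()
  if (!"ct" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'ct' is required")
  else {
    ct <- assay(object, "ct")
    maxc <- ctMaxCycle(object)
    bad <- which(!is.na(ct) & (ct < 0 | ct > maxc))
    if (length(bad))
      msg <- c(msg, sprintf("ct values outside [0, %g] at %d cell(s)",
                            maxc, length(bad)))
  }
  rd <- rowData(object)
  need <- c("mirna_name", "plate", "duplicate_group")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("missing rowData column(s): ",
                         paste(miss, collapse = ", ")))
  else {
    if (!all(rd$plate %in% c("A", "B")))
      msg <- c(msg, "plate must be 'A' or 'B'")
    dg <- as.character(rd$duplicate_group)
    grp <- dg[!is.na(dg) & nzchar(dg)]
    for (g in unique(grp)) {
      nm <- unique(rd$mirna_name[!is.na(dg) & dg == g])
      if (length(nm) > 1L)
        msg <- c(msg, sprintf(
          "duplicate_group '%s' spans distinct miRNA names: %s",
          g, paste(nm, collapse = ", ")))
    }
  }
  cd <- colData(object)
  if (!"group" %in% colnames(cd))
    msg <- c(msg, "missing colData column 'group'")
  else if (!all(as.character(cd$group) %in% c("knockdown", "control")))
    msg <- c(msg, "sample group must be 'knockdown' or 'control'")
  if (length(msg)) msg else TRUE
}
setValidity("CtExperiment", .validCtExperiment)

#' Construct a CtExperiment from a long CT table and a sample sheet
#'
#' @param ct data.frame in long form with columns `assay_id`, `mirna_name`,
#'   `plate`, `sample_id`, `ct` (numeric, `NA` = undetermined) and optionally
#'   `duplicate_group` (empty string = singleton assay), e.g. as returned by
#'   [readCtTable()].
#' @param samples data.frame with columns `sample_id`, `group`
#'   (`"knockdown"`/`"control"`) and optionally `label`, e.g. from
#'   [readSampleSheet()]. Column order of the returned object follows this
#'   sheet.
#' @param maxCycle maximum instrument cycle; numeric CTs must not exceed it.
#' @return a [CtExperiment-class] with assay `"ct"`. (assay, sample) pairs
#'   absent from `ct` are stored as `NA` (undetermined).
#' @examples
#' sim <- simulateLda(nFeatures = 20, nDuplicates = 2, seed = 1)
#' cte <- CtExperiment(sim$ct, sim$samples)
#' cte
#' @export
CtExperiment <- function(ct, samples, maxCycle = 40) {
  ct <- .validateCtLong(ct, maxCycle = maxCycle)
  samples <- .validateSampleSheet(samples)
  extra <- setdiff(unique(ct$sample_id), samples$sample_id)
  if (length(extra))
    stop("CT table sample_id(s) not in sample sheet: ",
         paste(extra, collapse = ", "), call. = FALSE)
  assays_ids <- unique(ct$assay_id)
  m <- matrix(NA_real_, length(assays_ids), nrow(samples),
              dimnames = list(assays_ids, samples$sample_id))
  m[cbind(match(ct$assay_id, assays_ids),
          match(ct$sample_id, samples$sample_id))] <- ct$ct
  first <- ct[!duplicated(ct$assay_id), , drop = FALSE]
  first <- first[match(assays_ids, first$assay_id), , drop = FALSE]
  rd <- DataFrame(mirna_name = first$mirna_name,
                  plate = first$plate,
                  duplicate_group = first$duplicate_group,
                  row.names = assays_ids)
  cd <- DataFrame(group = samples$group,
                  label = if ("label" %in% names(samples)) samples$label
                          else samples$sample_id,
                  row.names = samples$sample_id)
  se <- SummarizedExperiment(assays = list(ct = m), rowData = rd, colData = cd)
  metadata(se)$max_cycle <- maxCycle
  new("CtExperiment", se)
}
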