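#' Accessors for CtExperiment
#'
#' `ctValues()` returns the CT matrix (`NA` = undetermined), `mirnaNames()`,
#' `plates()` and `duplicateGroups()` the per-assay annotation (duplicate
#' group `""` for singleton assays), `sampleGroups()` the per-sample
#' knockdown/control factor, and `ctMaxCycle()` the instrument's maximum
#' cycle recorded at construction.
#'
#' @param x a [CtExperiment-class]
#' @return matrix, character vector, factor or scalar as described.
#' @name CtExperiment-accessors
NULL

#' @rdname CtExperiment-accessors
#' @export
setMethod("ctValues", "CtExperiment", function(x) assay(x, "ct"))

#' @rdname CtExperiment-accessors
#' @export
setMethod("mirnaNames", "CtExperiment", function(x)
  stats::setNames(as.character(rowData(x)$mirna_name), rownames(x)))

#' @rdname CtExperiment-accessors
#' @export
setMethod("plates", "CtExperiment", function(x)
  stats::setNames(as.character(rowData(x)$plate), rownames(x)))

#' @rdname CtExperiment-accessors
#' @export
setMethod("duplicateGroups", "CtExperiment", function(x) {
  dg <- as.character(rowData(x)$duplicate_group)
  dg[is.na(dg)] <- ""
  stats::setNames(dg, rownames(x))
})

#' @rdname CtExperiment-accessors
#' @export
setMethod("sampleGroups", "CtExperiment", function(x)
  stats::setNames(factor(as.character(colData(x)$group),
                         levels = c("knockdown", "control")),
                  colnames(x)))

#' @rdname CtExperiment-accessors
#' @export
setMethod("ctMaxCycle", "CtExperiment", function(x) {
  mc <- metadata(x)$max_cycle
  if (is.null(mc)) 40 else mc
})

setMethod("show", "CtExperiment", function(object) {
  ct <- ctValues(object)
  grp <- table(sampleGroups(object))
  dg <- duplicateGroups(object)
  cat(sprintf("CtExperiment: %d assays x %d samples\n", nrow(ct), ncol(ct)))
  cat(sprintf("  plates: %s\n",
              paste(sprintf("%s=%d", names(table(plates(object))),
                            table(plates(object))), collapse = ", ")))
  cat(sprintf("  duplicate groups: %d\n",
              length(unique(dg[nzchar(dg)]))))
  cat(sprintf("  samples: knockdown=%d, control=%d\n",
              grp[["knockdown"]], grp[["control"]]))
  cat(sprintf("  undetermined wells: %d (%.1f%%)\n",
              sum(is.na(ct)), 100 * mean(is.na(ct))))
  cat(sprintf("  max cycle: %g\n", ctMaxCycle(object)))
  invisible(NULL)
})
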