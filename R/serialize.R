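# JSON model serialization and scored-table output.

.selectorToList <- function(sel) {
  list(u = as.integer(sel@u), v = as.integer(sel@v))
}

.selectorFromList <- function(x) {
  new("ReferenceSelector", u = as.numeric(unlist(x$u)),
      v = as.numeric(unlist(x$v)))
}

#' Serialize a trained model to JSON
#'
#' Writes the selector bit-vectors and all trained parameters together with
#' a model tag and the tool version, so a scoring run can be reproduced from
#' the file alone. [readModel()] restores the model object.
#'
#' @param model a [FixvarModel-class] or [AdavarModel-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
setMethod("writeModel", "FixvarModel", function(model, path) {
  obj <- list(model_tag = "FIXVAR",
              version = as.character(packageVersion("adavar")),
              selector = .selectorToList(model@selector),
              mu_fix = model@muFix, sigma_fix = model@sigmaFix,
              train_depths = as.list(model@trainDepths),
              n_train = model@nTrain)
  write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
})

#' @rdname writeModel-FixvarModel-method
#' @export
setMethod("writeModel", "AdavarModel", function(model, path) {
  obj <- list(model_tag = "ADAVAR",
              version = as.character(packageVersion("adavar")),
              selector = .selectorToList(model@selector),
              p = model@p, q1 = model@q1, q2 = model@q2, c = model@c,
              combine_mode = model@combineMode,
              depth_grid = model@depthGrid,
              n_train = model@nTrain)
  write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
})

#' Restore a trained model from JSON
#'
#' @param path a JSON file written by [writeModel()].
#' @return a [FixvarModel-class] or [AdavarModel-class], depending on the
#'   file's `model_tag`.
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stopConfig("model file not found: %s", path)
  obj <- read_json(path, simplifyVector = TRUE)
  sel <- .selectorFromList(obj$selector)
  if (identical(obj$model_tag, "FIXVAR")) {
    new("FixvarModel", selector = sel, muFix = obj$mu_fix,
        sigmaFix = obj$sigma_fix,
        trainDepths = c(min = obj$train_depths$min,
                        median = obj$train_depths$median,
                        max = obj$train_depths$max),
        nTrain = as.integer(obj$n_train))
  } else if (identical(obj$model_tag, "ADAVAR")) {
    new("AdavarModel", selector = sel,
        p = setNames(as.numeric(obj$p), .AUTOSOMES),
        q1 = obj$q1, q2 = obj$q2, c = obj$c,
        combineMode = obj$combine_mode,
        depthGrid = as.numeric(obj$depth_grid),
        nTrain = as.integer(obj$n_train))
  } else {
    stopConfig("unknown model_tag in %s", path)
  }
}

#' Write a scored-sample table
#'
#' Tab-separated output of [fixvarZscore()] / [adavarZscore()] results with
#' a commented header carrying the tool version and free-form parameter
#' notes.
#'
#' @param scores data.frame as returned by the scoring functions.
#' @param path output TSV path.
#' @param notes optional character vector appended to the comment header.
#' @return `path`, invisibly.
#' @export
writeScores <- function(scores, path, notes = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.toolHeader(notes), con)
  suppressWarnings(write.table(scores, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}
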