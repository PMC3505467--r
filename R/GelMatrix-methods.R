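#' Construct a GelMatrix
#'
#' @param values numeric matrix, spots x gels, log2 relative percentage
#'   volumes with \code{NA} for missing cells.
#' @param groups character/factor of length \code{ncol(values)} with labels
#'   \code{"control"}/\code{"case"}.
#' @param spotIds,gelIds optional identifiers; default to the dimnames of
#'   \code{values} or generated labels.
#' @return A \linkS4class{GelMatrix}.
#' @examples
#' v <- matrix(c(-5, -4, NA, -6, -5.5, -4.2, -5.1, NA), nrow = 2)
#' gm <- gelMatrix(v, groups = c("control", "control", "case", "case"))
#' gelGroups(gm)
#' @export
gelMatrix <- function(values, groups, spotIds = rownames(values),
                      gelIds = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(spotIds)) spotIds <- paste0("spot", seq_len(nrow(values)))
  if (is.null(gelIds)) gelIds <- paste0("gel", seq_len(ncol(values)))
  groups <- factor(as.character(groups), levels = c("control", "case"))
  if (anyNA(groups))
    stop("group labels must be 'control' or 'case'")
  dimnames(values) <- list(as.character(spotIds), as.character(gelIds))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(group = groups, row.names = gelIds))
  new("GelMatrix", se)
}

#' @describeIn gelMatrix the spots-by-gels intensity matrix (NA = missing).
#' @param x a \code{GelMatrix}.
#' @export
intensityMatrix <- function(x) {
  stopifnot(is(x, "GelMatrix"))
  SummarizedExperiment::assay(x, "exprs")
}

#' @describeIn gelMatrix logical matrix, \code{TRUE} where the cell is missing.
#' @export
missingMask <- function(x) is.na(intensityMatrix(x))

#' @describeIn gelMatrix per-gel group factor (control/case).
#' @export
gelGroups <- function(x) {
  stopifnot(is(x, "GelMatrix"))
  SummarizedExperiment::colData(x)$group
}

#' @describeIn gelMatrix spot identifiers.
#' @export
spotIds <- function(x) rownames(x)

#' @describeIn gelMatrix gel identifiers.
#' @export
gelIds <- function(x) colnames(x)

setMethod("show", "GelMatrix", function(object) {
  g <- gelGroups(object)
  cat("GelMatrix:", nrow(object), "spots x", ncol(object), "gels (",
      sum(g == "control"), "control /", sum(g == "case"), "case )\n")
  cat("  missing cells:", sum(missingMask(object)),
      sprintf("(%.1f%%)\n", 100 * mean(missingMask(object))))
})

setMethod("show", "GlobalParams", function(object) {
  cat("GlobalParams:\n")
  v <- vapply(slotNames(object), function(s) slot(object, s), numeric(1))
  print(round(v, 4))
})

setMethod("show", "ChainTrace", function(object) {
  cat("ChainTrace:", nrow(object@samples), "retained states (",
      object@iterations, "iterations, thin", object@thin,
      ", burn-in", object@burninFrac, ")\n")
  cat("  spots:", length(object@spotIds), " seed:", object@seed, "\n")
})

setMethod("show", "SimulationScenario", function(object) {
  cat("SimulationScenario '", object@name, "': ", object@S, " spots, ",
      object@nControl, "+", object@nCase, " gels, d = ", object@d, "\n",
      sep = "")
})

setMethod("show", "SimulatedDataset", function(object) {
  cat("SimulatedDataset from scenario '", object@scenario@name, "'\n", sep = "")
  show(object@gelMatrix)
})

#' Accessors for ChainTrace and SimulatedDataset
#'
#' @param x a \linkS4class{ChainTrace} or \linkS4class{SimulatedDataset}.
#' @return \code{traceSamples}: the numeric matrix of recorded states;
#'   \code{traceSpotIds}: spot ids; \code{acceptanceRates}: per-block
#'   post-burn-in acceptance rates; \code{simGelMatrix}/\code{simTruth}: the
#'   simulated data and its generating truth table.
#' @name trace-accessors
NULL

#' @rdname trace-accessors
#' @export
traceSamples <- function(x) { stopifnot(is(x, "ChainTrace")); x@samples }

#' @rdname trace-accessors
#' @export
traceSpotIds <- function(x) { stopifnot(is(x, "ChainTrace")); x@spotIds }

#' @rdname trace-accessors
#' @export
acceptanceRates <- function(x) { stopifnot(is(x, "ChainTrace")); x@acceptance }

#' @rdname trace-accessors
#' @export
tunedAcceptanceRates <- function(x) {
  stopifnot(is(x, "ChainTrace"))
  x@tunedAcceptance
}

#' @rdname trace-accessors
#' @export
simGelMatrix <- function(x) { stopifnot(is(x, "SimulatedDataset")); x@gelMatrix }

#' @rdname trace-accessors
#' @export
simTruth <- function(x) { stopifnot(is(x, "SimulatedDataset")); x@truth }
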