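# Reading/writing spot-intensity tables and the raw -> log2 relative
# percent-volume preprocessing step.

.readTable <- function(path) {
  # sniff the delimiter: tab wins if present in the header line
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Read a spot-intensity table plus design into a GelMatrix
#'
#' The intensity table is tab- or comma-delimited with spot ids in the first
#' column and one column per gel; missing cells are the literal string
#' \code{"NA"} or empty.  The design maps each gel id to its group
#' (\code{control}/\code{case}): either a two-column file
#' (\code{gel_id}, \code{group}) or a named character vector.
#'
#' @param path path to the intensity table.
#' @param design path to a design file, or a named character vector of
#'   group labels (names = gel ids).
#' @return A \linkS4class{GelMatrix}.
#' @examples
#' tmp <- tempfile(); dsn <- tempfile()
#' writeLines(c("spot\tg1\tg2\tg3\tg4", "s1\t-5\t-4.5\tNA\t-5.2",
#'              "s2\tNA\t-6\t-5.8\t-6.1"), tmp)
#' writeLines(c("gel_id\tgroup", "g1\tcontrol", "g2\tcontrol",
#'              "g3\tcase", "g4\tcase"), dsn)
#' gm <- readIntensityTable(tmp, dsn)
#' sum(missingMask(gm))   # 2
#' @export
readIntensityTable <- function(path, design) {
  tab <- .readTable(path)
  spot_ids <- as.character(tab[[1L]])
  if (anyDuplicated(spot_ids))
    stop("duplicate spot ids: ",
         paste(unique(spot_ids[duplicated(spot_ids)]), collapse = ", "))
  gel_ids <- colnames(tab)[-1L]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (is.character(vals)) {
    # report any cell that is neither numeric nor a missing marker
    num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("non-numeric cell(s): ",
           paste(sprintf("row %s / gel %s", spot_ids[bad[, 1L]],
                         gel_ids[bad[, 2L]]), collapse = "; "))
    vals <- num
  }
  storage.mode(vals) <- "double"

  if (is.character(design) && length(design) == 1L && file.exists(design)) {
    dsn <- .readTable(design)
    if (ncol(dsn) < 2L) stop("design file needs columns gel_id, group")
    design <- setNames(as.character(dsn[[2L]]), as.character(dsn[[1L]]))
  }
  if (is.null(names(design)))
    stop("design must map gel ids to groups")
  absent <- setdiff(gel_ids, names(design))
  if (length(absent) > 0L)
    stop("gel(s) missing from the design: ", paste(absent, collapse = ", "))
  gelMatrix(vals, groups = design[gel_ids], spotIds = spot_ids,
            gelIds = gel_ids)
}

#' Write a GelMatrix (and its design) to tab-delimited files
#'
#' Missing cells are written as \code{"NA"}; a round trip through
#' \code{\link{readIntensityTable}} reproduces values, mask and groups.
#'
#' @param x a \linkS4class{GelMatrix}.
#' @param path output path for the intensity table.
#' @param designPath optional output path for the two-column design file.
#' @return Invisibly, \code{path}.
#' @export
writeGelMatrix <- function(x, path, designPath = NULL) {
  stopifnot(is(x, "GelMatrix"))
  df <- data.frame(spot_id = spotIds(x), intensityMatrix(x),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  if (!is.null(designPath)) {
    write.table(
      data.frame(gel_id = gelIds(x), group = as.character(gelGroups(x))),
      designPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Convert raw spot volumes to log2 relative percentage volumes
#'
#' Each gel (column) is scaled to its total raw volume so that spot values
#' become percentages of the gel, then log2-transformed:
#' \code{out[s, g] = log2(100 * raw[s, g] / sum(raw[, g]))}.  With 1000
#' equal-intensity spots every value is log2(0.1) (about -3.32); a spot
#' carrying a whole gel maps to log2(100) (about 6.64).  Raw zeros are
#' indistinguishable from non-detection and become missing.
#'
#' @param raw numeric matrix of non-negative raw spot volumes (spots x gels),
#'   \code{NA} for missing.
#' @return A numeric matrix of log2 percent volumes with \code{NA} for
#'   missing cells, suitable for [gelMatrix()].
#' @examples
#' raw <- matrix(rep(1, 10), ncol = 1)
#' toRelativeLog2(raw)[1, 1]  # log2(10)
#' @export
toRelativeLog2 <- function(raw) {
  raw <- as.matrix(raw)
  storage.mode(raw) <- "double"
  if (any(raw < 0, na.rm = TRUE)) stop("raw volumes must be >= 0")
  raw[!is.na(raw) & raw == 0] <- NA_real_
  tot <- colSums(raw, na.rm = TRUE)
  dead <- tot <= 0
  if (any(dead))
    stop("gel(s) with no positive volume: ",
         paste(if (is.null(colnames(raw))) which(dead) else
               colnames(raw)[dead], collapse = ", "))
  out <- log2(sweep(raw, 2L, tot / 100, "/"))
  dimnames(out) <- dimnames(raw)
  out
}
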