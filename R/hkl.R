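#' Construct a reflection set
#'
#' @param hkl n x 3 integer matrix of Miller indices
#' @param fo |F_obs| values (electrons)
#' @param sigma standard uncertainties of |F_obs|
#' @param dialect provenance label
#' @return a \code{ReflectionSet}
#' @export
reflectionSet <- function(hkl, fo, sigma, dialect = "F") {
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  storage.mode(hkl) <- "integer"
  new("ReflectionSet", hkl = hkl, fo = as.numeric(fo),
      sigma = as.numeric(sigma), observed = rep(TRUE, nrow(hkl)),
      dialect = dialect)
}

#' Detect the dialect of a reflection file
#'
#' SHELX files are fixed-width (3I4, 2F8); free-format files are
#' whitespace-delimited. Record width separates the two families, but F and
#' F^2 content cannot be distinguished from the records themselves, so
#' fixed-width files are reported as \code{"shelx_F2"} (the common SHELX
#' convention) and should be overridden with an explicit dialect when they
#' carry F.
#'
#' @param lines character vector of data lines
#' @return one of "shelx_F2", "F"
#' @export
detectHklDialect <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  probe <- utils::head(lines, 25)
  fixed <- all(vapply(probe, function(ln) {
    nchar(ln) >= 28 &&
      !anyNA(suppressWarnings(as.numeric(c(substr(ln, 1, 4), substr(ln, 5, 8),
                                           substr(ln, 9, 12), substr(ln, 13, 20),
                                           substr(ln, 21, 28)))))
  }, logical(1)))
  if (fixed) "shelx_F2" else "F"
}

#' Parse a reflection file
#'
#' Reads SHELX-style fixed-width records (3I4, 2F8) or whitespace-delimited
#' columns \code{h k l value sigma}. F^2 dialects are converted to |F| with
#' \eqn{\sigma_F = \sigma_{F^2} / (2|F|)}; non-positive F^2 values are
#' truncated to |F| = 0 with \eqn{\sigma_F = \sqrt{\sigma_{F^2}}} and a
#' message. A terminator record \code{0 0 0} stops parsing.
#'
#' @param text a file path or the file content as a character vector
#' @param dialect one of "F", "F2", "shelx_F", "shelx_F2", or "auto"
#' @return a \code{ReflectionSet}
#' @export
parseHkl <- function(text, dialect = "auto") {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- text[nzchar(trimws(text))]
  if (!length(lines)) stop("empty reflection file")
  if (dialect == "auto") dialect <- detectHklDialect(lines)
  if (!dialect %in% c("F", "F2", "shelx_F", "shelx_F2"))
    stop("unknown hkl dialect: ", dialect)
  fixed <- startsWith(dialect, "shelx")
  squared <- dialect %in% c("F2", "shelx_F2")

  rec <- matrix(NA_real_, length(lines), 5)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    v <- if (fixed) {
      suppressWarnings(as.numeric(c(substr(ln, 1, 4), substr(ln, 5, 8),
                                    substr(ln, 9, 12), substr(ln, 13, 20),
                                    substr(ln, 21, 28))))
    } else {
      suppressWarnings(as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]][1:5]))
    }
    if (anyNA(v[1:3]))
      stop("malformed reflection record at line ", i, ": ", ln)
    if (all(v[1:3] == 0)) { rec <- rec[seq_len(i - 1L), , drop = FALSE]; break }
    if (anyNA(v[4:5]))
      stop("malformed reflection record at line ", i, ": ", ln)
    rec[i, ] <- v
  }
  rec <- rec[stats::complete.cases(rec), , drop = FALSE]
  if (!nrow(rec)) stop("reflection file contains no data records")
  hkl <- rec[, 1:3, drop = FALSE]
  val <- rec[, 4]; sig <- rec[, 5]
  if (squared) {
    neg <- val <= 0
    f <- sqrt(pmax(val, 0))
    sf <- ifelse(neg, sqrt(pmax(sig, .Machine$double.eps)),
                 sig / (2 * pmax(f, .Machine$double.eps)))
    if (any(neg))
      message(sum(neg), " non-positive F^2 record(s) truncated to |F| = 0")
    val <- f; sig <- sf
  }
  if (all(val <= 0))
    stop("refusing reflection file: every reflection is non-positive")
  if (any(sig <= 0)) {
    message(sum(sig <= 0), " record(s) with non-positive sigma assigned a ",
            "nominal uncertainty")
    sig[sig <= 0] <- 1e-4 * max(val)
  }
  reflectionSet(round(hkl), val, sig, dialect = dialect)
}

#' Write reflections in SHELX fixed format
#'
#' @param refl a \code{ReflectionSet}
#' @param path optional output file
#' @param squared write F^2 records instead of F
#' @return text lines, invisibly when written
#' @export
writeHkl <- function(refl, path = NULL, squared = FALSE) {
  v <- refl@fo; s <- refl@sigma
  if (squared) { s <- 2 * v * s; v <- v^2 }
  # four decimals still fit the fixed 8-character SHELX fields for the
  # magnitudes handled here and keep small-molecule sigmas representable
  dec <- if (max(v, s) < 1000) 4L else 2L
  lines <- sprintf("%4d%4d%4d%8.*f%8.*f", refl@hkl[, 1], refl@hkl[, 2],
                   refl@hkl[, 3], dec, v, dec, s)
  lines <- c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0L, 0L, 0L, 0, 0))
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Prune reflections for refinement
#'
#' Applies an observation predicate (default: F > 3 sigma(F)) and reports the
#' kept/removed counts. Pruning sets the \code{observed} flag; the index set
#' itself is preserved.
#'
#' @param refl a \code{ReflectionSet}
#' @param predicate function(fo, sigma) -> logical, or NULL for the default
#' @param sigmaCut cutoff used by the default predicate
#' @return the \code{ReflectionSet} with updated flags and a "report" attribute
#' @export
pruneReflections <- function(refl, predicate = NULL, sigmaCut = 3) {
  keep <- if (is.null(predicate)) refl@fo > sigmaCut * refl@sigma
          else predicate(refl@fo, refl@sigma)
  if (!any(keep)) stop("pruning removed every reflection")
  refl@observed <- keep
  attr(refl, "report") <- sprintf("pruning kept %d of %d reflections (removed %d)",
                                  sum(keep), length(keep), sum(!keep))
  refl
}
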