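# --- low-level CIF tokenizer ---------------------------------------------

cifTokenize <- function(lines) {
  tokens <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ";")) {            # multi-line text field
      txt <- character()
      i <- i + 1L
      while (i <= length(lines) && !startsWith(lines[i], ";")) {
        txt <- c(txt, lines[i]); i <- i + 1L
      }
      tokens[[length(tokens) + 1L]] <- paste(txt, collapse = "\n")
      i <- i + 1L
      next
    }
    ln <- sub("^#.*$", "", ln)
    pos <- 1L
    n <- nchar(ln)
    while (pos <= n) {
      ch <- substr(ln, pos, pos)
      if (grepl("^[ \t]$", ch)) { pos <- pos + 1L; next }
      if (ch == "#") break
      if (ch == "'" || ch == "\"") {
        end <- regexpr(ch, substr(ln, pos + 1L, n), fixed = TRUE)
        if (end < 0) stop("unterminated quoted string in CIF line: ", ln)
        tokens[[length(tokens) + 1L]] <- substr(ln, pos + 1L, pos + end - 1L)
        pos <- pos + end + 1L
      } else {
        rest <- substr(ln, pos, n)
        tok <- regmatches(rest, regexpr("^[^ \t]+", rest))
        tokens[[length(tokens) + 1L]] <- tok
        pos <- pos + nchar(tok)
      }
    }
    i <- i + 1L
  }
  unlist(tokens)
}

# Parse a CIF document into scalar items and loops
cifDocument <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  toks <- cifTokenize(lines)
  items <- list(); loops <- list()
  i <- 1L
  isTag <- function(x) startsWith(x, "_")
  while (i <= length(toks)) {
    tk <- toks[i]
    if (grepl("^data_", tk, ignore.case = TRUE) ||
        grepl("^global_", tk, ignore.case = TRUE)) { i <- i + 1L; next }
    if (tolower(tk) == "loop_") {
      i <- i + 1L
      tags <- character()
      while (i <= length(toks) && isTag(toks[i])) {
        tags <- c(tags, tolower(toks[i])); i <- i + 1L
      }
      vals <- character()
      while (i <= length(toks) && !isTag(toks[i]) &&
             tolower(toks[i]) != "loop_" &&
             !grepl("^data_", toks[i], ignore.case = TRUE)) {
        vals <- c(vals, toks[i]); i <- i + 1L
      }
      if (length(tags) && length(vals) %% length(tags) == 0L) {
        m <- matrix(vals, ncol = length(tags), byrow = TRUE)
        colnames(m) <- tags
        loops[[length(loops) + 1L]] <- as.data.frame(m, stringsAsFactors = FALSE)
      } else if (length(tags)) {
        stop("malformed CIF loop (", length(vals), " values for ",
             length(tags), " tags): ", tags[1])
      }
      next
    }
    if (isTag(tk)) {
      if (i + 1L <= length(toks)) {
        items[[tolower(tk)]] <- toks[i + 1L]
        i <- i + 2L
      } else i <- i + 1L
      next
    }
    i <- i + 1L
  }
  list(items = items, loops = loops)
}

# "4.265(1)" -> c(value, su); "." / "?" -> NA
cifNumber <- function(s) {
  if (is.na(s) || s %in% c(".", "?")) return(c(NA_real_, 0))
  m <- regmatches(s, regexec("^([-+0-9.eE]+)(\\(([0-9]+)\\))?$", s))[[1]]
  if (length(m) == 0L || !nzchar(m[2])) return(c(NA_real_, 0))
  v <- suppressWarnings(as.numeric(m[2]))
  su <- 0
  if (nzchar(m[4])) {
    dec <- if (grepl("\\.", m[2])) nchar(sub("^[^.]*\\.", "", m[2])) else 0L
    su <- as.numeric(m[4]) * 10^(-dec)
  }
  c(v, su)
}

findLoop <- function(doc, tag) {
  for (lp in doc$loops) if (tag %in% colnames(lp)) return(lp)
  NULL
}

# --- structure construction ----------------------------------------------

emptySites <- function(n) {
  data.frame(label = character(n), element = character(n),
             x = numeric(n), y = numeric(n), z = numeric(n),
             occ = rep(1, n), adpType = rep("iso", n),
             uiso = numeric(n),
             u11 = numeric(n), u22 = numeric(n), u33 = numeric(n),
             u12 = numeric(n), u13 = numeric(n), u23 = numeric(n),
             su_x = numeric(n), su_y = numeric(n), su_z = numeric(n),
             su_uiso = numeric(n),
             su_u11 = numeric(n), su_u22 = numeric(n), su_u33 = numeric(n),
             su_u12 = numeric(n), su_u13 = numeric(n), su_u23 = numeric(n),
             mult = rep(1L, n), stringsAsFactors = FALSE)
}

#' Construct a crystal structure
#'
#' Assembles a \linkS4class{CrystalStructure} from a cell, symmetry
#' operations and a site table; fills missing site columns with defaults and
#' computes site multiplicities from the stabilizers.
#'
#' @param cell a \code{UnitCell}
#' @param symops list of \code{SymOp} (default P1)
#' @param sites data.frame with at least label, element, x, y, z
#' @param spaceGroupName informational symbol
#' @param Z formula units per cell (default number of symops)
#' @return a \code{CrystalStructure}
#' @export
crystalStructure <- function(cell, symops = list(parseSymOp("x, y, z")),
                             sites, spaceGroupName = "", Z = NA) {
  full <- emptySites(nrow(sites))
  for (nm in names(sites)) if (nm %in% names(full)) full[[nm]] <- sites[[nm]]
  if (!"adpType" %in% names(sites))
    full$adpType <- ifelse(rowSums(abs(full[c("u11","u22","u33")])) > 0, "ani", "iso")
  s <- new("CrystalStructure", cell = cell, symops = symops, sites = full,
           spaceGroupName = spaceGroupName,
           Z = if (is.na(Z)) length(symops) else Z)
  s@sites$mult <- vapply(seq_len(nrow(full)), function(i)
    as.integer(sitePositionConstraints(s, i)$multiplicity), integer(1))
  validObject(s)
  s
}

#' Parse a crystallographic information file
#'
#' Reads the core-CIF subset needed for refinement: cell parameters,
#' symmetry operations (explicit \code{_symmetry_equiv_pos_as_xyz} or
#' \code{_space_group_symop_operation_xyz} loop; bare P1/P-1 symbols are also
#' accepted), the \code{_atom_site} loop and, when present, the
#' \code{_atom_site_aniso} loop joined by label. Fractional coordinates are
#' normalized into [0, 1); sites without any displacement parameter default
#' to U_iso = 0.02 \eqn{\AA^2} with a warning.
#'
#' @param text a file path, or CIF content as a character vector
#' @return a \code{CrystalStructure}
#' @export
parseCif <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  doc <- cifDocument(text)
  it <- doc$items
  num <- function(tag) {
    v <- it[[tag]]
    if (is.null(v)) stop("CIF parse error: required item '", tag, "' is absent")
    cifNumber(v)[1]
  }
  for (tag in c("_cell_length_a", "_cell_length_b", "_cell_length_c",
                "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma"))
    if (is.null(it[[tag]]))
      stop("CIF parse error: required item '", tag, "' is absent")
  cell <- unitCell(num("_cell_length_a"), num("_cell_length_b"),
                   num("_cell_length_c"), num("_cell_angle_alpha"),
                   num("_cell_angle_beta"), num("_cell_angle_gamma"))

  symLoop <- findLoop(doc, "_symmetry_equiv_pos_as_xyz")
  symTag <- "_symmetry_equiv_pos_as_xyz"
  if (is.null(symLoop)) {
    symLoop <- findLoop(doc, "_space_group_symop_operation_xyz")
    symTag <- "_space_group_symop_operation_xyz"
  }
  sgName <- it[["_symmetry_space_group_name_h-m"]]
  if (is.null(sgName)) sgName <- it[["_space_group_name_h-m_alt"]]
  if (is.null(sgName)) sgName <- ""
  if (!is.null(symLoop)) {
    symops <- lapply(symLoop[[symTag]], parseSymOp)
  } else {
    compact <- gsub(" ", "", sgName)
    if (compact %in% c("P1", "")) {
      symops <- list(parseSymOp("x, y, z"))
    } else if (compact == "P-1") {
      symops <- list(parseSymOp("x, y, z"), parseSymOp("-x, -y, -z"))
    } else {
      stop("CIF parse error: no symmetry operations loop, and space-group ",
           "symbol '", sgName, "' is not one of the symbols understood ",
           "without one (P1, P-1)")
    }
  }
  cl <- checkSymOpClosure(symops)
  if (!isTRUE(cl)) stop("CIF symmetry error: ", cl)

  siteLoop <- findLoop(doc, "_atom_site_label")
  if (is.null(siteLoop))
    stop("CIF parse error: required loop '_atom_site_label' is absent")
  n <- nrow(siteLoop)
  sites <- emptySites(n)
  sites$label <- siteLoop[["_atom_site_label"]]
  sites$element <- if ("_atom_site_type_symbol" %in% names(siteLoop)) {
    vapply(siteLoop[["_atom_site_type_symbol"]], function(s) {
      e <- elementFromLabel(s)
      if (is.na(e)) s else e
    }, character(1), USE.NAMES = FALSE)
  } else vapply(sites$label, elementFromLabel, character(1), USE.NAMES = FALSE)
  bad <- which(is.na(sites$element) | !(sites$element %in% ELEMENTS))
  if (length(bad))
    stop("unknown element symbol for site label(s): ",
         paste(sites$label[bad], collapse = ", "))
  getCol <- function(tag, default = NA_real_) {
    if (!tag %in% names(siteLoop)) return(list(v = rep(default, n), su = rep(0, n)))
    p <- t(vapply(siteLoop[[tag]], cifNumber, numeric(2), USE.NAMES = FALSE))
    list(v = p[, 1], su = p[, 2])
  }
  fx <- getCol("_atom_site_fract_x"); fy <- getCol("_atom_site_fract_y")
  fz <- getCol("_atom_site_fract_z")
  if (anyNA(fx$v) || anyNA(fy$v) || anyNA(fz$v))
    stop("CIF parse error: required item '_atom_site_fract_*' is absent or invalid")
  sites$x <- fx$v %% 1; sites$y <- fy$v %% 1; sites$z <- fz$v %% 1
  sites$su_x <- fx$su; sites$su_y <- fy$su; sites$su_z <- fz$su
  occ <- getCol("_atom_site_occupancy", 1)
  sites$occ <- ifelse(is.na(occ$v), 1, occ$v)
  ui <- getCol("_atom_site_u_iso_or_equiv")
  sites$uiso <- ui$v; sites$su_uiso <- ui$su

  aniLoop <- findLoop(doc, "_atom_site_aniso_label")
  if (!is.null(aniLoop)) {
    tags <- paste0("_atom_site_aniso_u_", c("11", "22", "33", "12", "13", "23"))
    cols <- c("u11", "u22", "u33", "u12", "u13", "u23")
    idx <- match(aniLoop[["_atom_site_aniso_label"]], sites$label)
    if (anyNA(idx))
      stop("aniso loop refers to unknown site label(s): ",
           paste(aniLoop[["_atom_site_aniso_label"]][is.na(idx)], collapse = ", "))
    for (j in seq_along(tags)) {
      if (!tags[j] %in% names(aniLoop)) next
      p <- t(vapply(aniLoop[[tags[j]]], cifNumber, numeric(2), USE.NAMES = FALSE))
      sites[[cols[j]]][idx] <- p[, 1]
      sites[[paste0("su_", cols[j])]][idx] <- p[, 2]
    }
    sites$adpType[idx] <- "ani"
  }
  noAdp <- sites$adpType == "iso" & is.na(sites$uiso)
  if (any(noAdp)) {
    warning("no displacement parameters for site(s) ",
            paste(sites$label[noAdp], collapse = ", "),
            "; defaulting to U_iso = 0.02 A^2")
    sites$uiso[noAdp] <- 0.02
  }
  sites$uiso[is.na(sites$uiso)] <- 0

  zv <- it[["_cell_formula_units_z"]]
  crystalStructure(cell, symops, sites, spaceGroupName = sgName,
                   Z = if (is.null(zv)) NA else cifNumber(zv)[1])
}

# --- writing -------------------------------------------------------------

#' Format a value with its standard uncertainty in CIF notation
#'
#' Standard crystallographic convention: the s.u. is quoted in parentheses in
#' units of the least significant digit, using two digits when the leading
#' s.u. digit is 1 and one digit otherwise. A zero s.u. (fixed parameter)
#' gives a bare number.
#'
#' @param value numeric value
#' @param su its standard uncertainty (0 for fixed)
#' @param fixedDigits decimals used when su = 0
#' @return character
#' @examples
#' formatSu(1.0440, 0.0012)   # "1.0440(12)"
#' @export
formatSu <- function(value, su, fixedDigits = 6) {
  if (is.na(su) || su <= 0) return(sprintf("%.*f", fixedDigits, value))
  e <- floor(log10(su))
  digits <- if (su / 10^e < 2) 2L else 1L
  dec <- max(0L, -(e - digits + 1L))
  suInt <- round(su * 10^dec)
  if (suInt >= 10^digits) {          # rounding carried over (e.g. 0.0199)
    suInt <- round(suInt / 10)
    dec <- dec - 1L
    if (dec < 0L) { dec <- 0L; suInt <- suInt }
  }
  sprintf("%.*f(%d)", dec, value, as.integer(suInt))
}

#' Write a crystal structure as CIF
#'
#' Plain geometry output (no uncertainties) used for fixtures and round-trip
#' checks; see \code{\link{writeCifResult}} for refinement output.
#'
#' @param structure a \code{CrystalStructure}
#' @param path optional output file
#' @return the CIF text, invisibly when written to a file
#' @export
writeCif <- function(structure, path = NULL) {
  txt <- cifText(structure, result = NULL)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Write a refinement result as CIF
#'
#' Emits refined coordinates and displacement parameters with s.u.s in
#' parenthesized CIF notation, the scale factor, R factors, reflection and
#' parameter counts, and refinement flags.
#'
#' @param structure the refined \code{CrystalStructure} (usually
#'   \code{refinedStructure(result)})
#' @param result a \code{RefinementResult}
#' @param path optional output file
#' @return the CIF text, invisibly when written to a file
#' @export
writeCifResult <- function(structure, result, path = NULL) {
  txt <- cifText(structure, result)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

cifText <- function(structure, result = NULL) {
  cell <- structure@cell
  s <- structure@sites
  # plain output keeps full precision (su in units of 1e-6) so that a
  # write/parse round trip is numerically faithful; refinement output uses
  # the conventional su-truncated notation
  fmt <- if (is.null(result)) {
    function(v, su) if (is.na(su) || su <= 0) sprintf("%.6f", v)
                    else sprintf("%.6f(%d)", v, as.integer(round(su * 1e6)))
  } else function(v, su) formatSu(v, su)
  out <- c("data_qcrefine",
           sprintf("_cell_length_a    %.6f", cell@a),
           sprintf("_cell_length_b    %.6f", cell@b),
           sprintf("_cell_length_c    %.6f", cell@c),
           sprintf("_cell_angle_alpha %.6f", cell@alpha),
           sprintf("_cell_angle_beta  %.6f", cell@beta),
           sprintf("_cell_angle_gamma %.6f", cell@gamma),
           sprintf("_cell_volume      %.6f", cell@volume))
  if (nzchar(structure@spaceGroupName))
    out <- c(out, sprintf("_symmetry_space_group_name_H-M '%s'",
                          structure@spaceGroupName))
  if (!is.na(structure@Z))
    out <- c(out, sprintf("_cell_formula_units_Z %d", as.integer(structure@Z)))
  out <- c(out, "loop_", "_symmetry_equiv_pos_as_xyz",
           vapply(structure@symops, function(o)
             sprintf("  '%s'", symOpToString(o)), character(1)))
  if (!is.null(result)) {
    out <- c(out,
             sprintf("_refine_ls_R_factor_gt    %.6f", result@r1),
             sprintf("_refine_ls_wR_factor_ref  %.6f", result@wr2),
             sprintf("_refine_ls_goodness_of_fit_ref %.4f", result@gof),
             sprintf("_refine_ls_number_reflns  %d", as.integer(result@nObs)),
             sprintf("_refine_ls_number_parameters %d", as.integer(result@nParam)),
             sprintf("_refine_ls_scale_factor %s", fmt(result@k, result@suK)),
             sprintf("_refine_ls_converged %s",
                     if (result@converged) "yes" else "no"))
    if (length(result@flags))
      out <- c(out, sprintf("_refine_special_details '%s'",
                            paste(unlist(result@flags), collapse = "; ")))
  }
  out <- c(out, "loop_", "_atom_site_label", "_atom_site_type_symbol",
           "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
           "_atom_site_U_iso_or_equiv", "_atom_site_occupancy")
  for (i in seq_len(nrow(s))) {
    uiso <- if (s$adpType[i] == "ani") mean(c(s$u11[i], s$u22[i], s$u33[i]))
            else s$uiso[i]
    out <- c(out, sprintf("  %s %s %s %s %s %s %.4f",
                          s$label[i], s$element[i],
                          fmt(s$x[i], s$su_x[i]), fmt(s$y[i], s$su_y[i]),
                          fmt(s$z[i], s$su_z[i]),
                          fmt(uiso, if (s$adpType[i] == "iso") s$su_uiso[i] else 0),
                          s$occ[i]))
  }
  ani <- which(s$adpType == "ani")
  if (length(ani)) {
    out <- c(out, "loop_", "_atom_site_aniso_label",
             paste0("_atom_site_aniso_U_", c("11", "22", "33", "12", "13", "23")))
    for (i in ani) {
      out <- c(out, sprintf("  %s %s %s %s %s %s %s", s$label[i],
                            fmt(s$u11[i], s$su_u11[i]), fmt(s$u22[i], s$su_u22[i]),
                            fmt(s$u33[i], s$su_u33[i]), fmt(s$u12[i], s$su_u12[i]),
                            fmt(s$u13[i], s$su_u13[i]), fmt(s$u23[i], s$su_u23[i])))
    }
  }
  paste(out, collapse = "\n")
}
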