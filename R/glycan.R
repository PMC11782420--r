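# LinearCode glycan representation and Oxford-style compositional tags.

#: residue token -> monosaccharide name (N-glycan subset of LinearCode)
.LC_RESIDUES <- c(M = "Man", GN = "GlcNAc", A = "Gal", F = "Fuc",
                  NN = "Neu5Ac", G = "Glc")

.MONOSACCHARIDES <- c("Man", "GlcNAc", "Gal", "Fuc", "Neu5Ac", "Glc")

#' Parse a LinearCode glycan string
#'
#' Tokenizes the N-glycan subset of LinearCode (residues `M` = mannose,
#' `GN` = N-acetylglucosamine, `A` = galactose, `F` = fucose, `NN` =
#' N-acetylneuraminic acid, `G` = glucose; anomeric tokens `a`/`b` with
#' linkage digits 1-6; branches in parentheses; reducing end rightmost)
#' and returns the monosaccharide composition together with structural
#' flags needed for tag assignment.
#'
#' @param code LinearCode string, e.g. `"GNb2Ma3(GNb2Ma6)Mb4GNb4GN"`.
#'   An optional trailing `";"` is tolerated.
#' @return An object of class `glycan_structure`: a list with elements
#'   `linear_code`, `composition` (named integer vector over Man, GlcNAc,
#'   Gal, Fuc, Neu5Ac, Glc), `core_fucose` (logical: a fucose branch on the
#'   reducing-end GlcNAc), `antennae` (GlcNAc count beyond the two core
#'   residues) and `tag` (Oxford-style compositional tag).
#' @examples
#' g <- parse_linear_code("GNb2Ma3(GNb2Ma6)Mb4GNb4GN")
#' g$composition[["Man"]]   # 3
#' g$tag                    # "A2"
#' @export
parse_linear_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code) || !nzchar(code))
    stop("LinearCode parse error: input must be a single non-empty string")
  raw <- sub(";$", "", code)
  if (!nzchar(raw))
    stop("LinearCode parse error: empty structure")

  comp <- stats::setNames(integer(length(.MONOSACCHARIDES)), .MONOSACCHARIDES)
  i <- 1L
  n <- nchar(raw)
  depth <- 0L
  expect_residue <- TRUE   # a linkage token must follow a residue
  while (i <= n) {
    ch <- substr(raw, i, i)
    if (ch == "(") {
      depth <- depth + 1L
      i <- i + 1L
      expect_residue <- TRUE
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("LinearCode parse error: unbalanced parentheses in '", code, "'")
      i <- i + 1L
      expect_residue <- TRUE
    } else if (ch %in% c("a", "b") && !expect_residue) {
      # anomeric configuration, optionally followed by linkage digit(s)
      i <- i + 1L
      while (i <= n && grepl("[1-6]", substr(raw, i, i))) i <- i + 1L
      expect_residue <- TRUE
    } else {
      two <- substr(raw, i, i + 1L)
      if (two %in% names(.LC_RESIDUES)) {
        comp[[.LC_RESIDUES[[two]]]] <- comp[[.LC_RESIDUES[[two]]]] + 1L
        i <- i + 2L
      } else if (ch %in% names(.LC_RESIDUES)) {
        comp[[.LC_RESIDUES[[ch]]]] <- comp[[.LC_RESIDUES[[ch]]]] + 1L
        i <- i + 1L
      } else {
        stop("LinearCode parse error: unknown residue token '", ch,
             "' at position ", i, " in '", code, "'")
      }
      expect_residue <- FALSE
    }
  }
  if (depth != 0L)
    stop("LinearCode parse error: unbalanced parentheses in '", code, "'")

  core_fuc <- .has_core_fucose(raw)
  antennae <- max(0L, comp[["GlcNAc"]] - 2L)
  g <- structure(
    list(linear_code = code,
         composition = comp,
         core_fucose = core_fuc,
         antennae = antennae,
         tag = NA_character_),
    class = "glycan_structure")
  g$tag <- composition_to_tag(g, core_fucose = core_fuc, antennae = antennae)
  g
}

# Core fucose: a parenthesised fucose branch attached to the reducing-end
# (rightmost) GlcNAc, i.e. the string ends "...(Fa6)GN" / "...(Fa3)GN".
.has_core_fucose <- function(raw) {
  grepl("\\(F[ab]?[1-6]?\\)GN$", raw)
}

#' Oxford-style compositional tag from a glycan composition
#'
#' Maps a monosaccharide composition to a compositional tag: high-mannose
#' structures give `"M"` plus the mannose count (e.g. `M5`); hybrid
#' structures with retained mannose give `"M{n}A{m}"` (e.g. `M5A1`);
#' complex structures give an optional `"F"` prefix for core fucose,
#' `"A"` plus antenna count, then `"G"`/`"S"` counts for galactose and
#' sialic acid when positive (e.g. `FA2G2S1`). The trimmed
#' Man3GlcNAc2 core with no antennae is tagged `"A0"`.
#'
#' @param g A `glycan_structure` (or any list with a `composition` element).
#' @param core_fucose Logical; is a core fucose present?
#' @param antennae Integer; antenna GlcNAc count beyond the two core
#'   residues. Defaults to `GlcNAc - 2`.
#' @return A single tag string.
#' @examples
#' composition_to_tag(list(composition = c(Man = 5, GlcNAc = 2, Gal = 0,
#'   Fuc = 0, Neu5Ac = 0, Glc = 0)), core_fucose = FALSE, antennae = 0)  # "M5"
#' @export
composition_to_tag <- function(g, core_fucose = NULL, antennae = NULL) {
  comp <- g$composition
  if (is.null(comp)) stop("composition error: composition not populated")
  comp <- comp[.MONOSACCHARIDES[.MONOSACCHARIDES %in% names(comp)]]
  full <- stats::setNames(integer(length(.MONOSACCHARIDES)), .MONOSACCHARIDES)
  full[names(comp)] <- as.integer(comp)
  if (any(full < 0)) stop("composition error: negative monosaccharide count")
  if (full[["GlcNAc"]] < 2L)
    stop("composition error: N-glycan requires the chitobiose core (GlcNAc >= 2)")
  if (is.null(core_fucose)) core_fucose <- isTRUE(g$core_fucose)
  if (is.null(antennae)) antennae <- max(0L, full[["GlcNAc"]] - 2L)
  antennae <- as.integer(antennae)
  if (antennae < 0L) stop("composition error: negative antenna count")
  if (full[["Gal"]] > 0L && antennae > 0L && full[["Gal"]] > antennae)
    stop("composition error: more galactoses (", full[["Gal"]],
         ") than antennae (", antennae, ")")

  man <- full[["Man"]]; gal <- full[["Gal"]]; sia <- full[["Neu5Ac"]]
  fuc <- full[["Fuc"]]
  if (antennae == 0L && gal == 0L && sia == 0L && fuc == 0L) {
    # high-mannose series (or the bare trimmed core)
    if (man >= 4L) return(paste0("M", man))
    return("A0")
  }
  if (man > 3L) {
    # hybrid: retained mannose alongside antenna GlcNAc
    return(paste0("M", man, if (antennae > 0L) paste0("A", antennae)))
  }
  paste0(if (core_fucose) "F",
         "A", antennae,
         if (gal > 0L) paste0("G", gal),
         if (sia > 0L) paste0("S", sia))
}

#' Nodes of a reaction network carrying a compositional tag
#'
#' A single tag can correspond to several structural isomorphs (e.g. a
#' monogalactosylated biantennary glycan with the galactose on either
#' arm); this returns every node whose `tag` attribute matches.
#'
#' @param net A `glyco_grn` reaction network.
#' @param tag Compositional tag string.
#' @return Character vector of node identifiers (possibly empty).
#' @export
tag_to_nodes <- function(net, tag) {
  stopifnot(inherits(net, "glyco_grn"))
  v <- igraph::V(net$graph)
  as.character(v$name[v$tag == tag])
}

#' @export
print.glycan_structure <- function(x, ...) {
  comp <- x$composition[x$composition > 0]
  cat("<glycan_structure> ", x$tag, "\n",
      "  LinearCode: ", x$linear_code, "\n",
      "  composition: ",
      paste(names(comp), comp, sep = ":", collapse = " "), "\n", sep = "")
  invisible(x)
}
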