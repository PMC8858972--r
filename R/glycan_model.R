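# Monoisotopic residue masses (Da): glycosidic-bond residues, i.e. the
# monosaccharide minus one water. One water is added back per glycan for the
# free reducing end.
RESIDUE_MASS <- c(
  hexnac = 203.079373,
  hex    = 162.052824,
  fuc    = 146.057909,
  neuac  = 291.095417
)
WATER_MASS <- 18.010565

# Cation masses for singly charged positive-mode adducts. "M+2Na-H" is
# bookkept as 2*(Na+) - (H+).
ADDUCT_MASS <- c(
  "M+H"     = 1.007276,
  "M+Na"    = 22.989218,
  "M+2Na-H" = 44.971160
)

CHANNELS <- c(G = "IgG", G1 = "IgG1", G2 = "IgG2", G3 = "IgG3", G4 = "IgG4")

#' Parse an Oxford-nomenclature glycan name
#'
#' Oxford names describe an N-glycan composition over the constant
#' trimannosyl-chitobiose core (two core GlcNAcs, three mannoses):
#' `A<x>` gives the number of antennary GlcNAcs, an optional `B` a bisecting
#' GlcNAc, `G<x>` the number of galactoses, an optional `S<x>` the number of
#' sialic acids (N-acetylneuraminic acids) and an optional `F` a core fucose.
#' `F` is accepted either before or after the `S` block; the canonical form
#' printed by [format_oxford()] places it last.
#'
#' @param name Oxford glycan name, e.g. `"A2BG0F"` or `"A2G2S1"`.
#' @return An object of class `glycan_composition`: a list with counts
#'   `hexnac`, `hex`, `fuc`, `neuac`, the flag `bisecting`, and the
#'   structural counts `antennae` and `galactose`.
#' @examples
#' parse_oxford("A2G0F")
#' parse_oxford("A2BG2S1F")
#' @export
parse_oxford <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  s <- gsub("\\s+", "", name)
  m <- regmatches(s, regexec(
    "^A([0-9])(B?)G([0-9])(?:F(?=S|$))?(?:S([0-9]))?(F?)$", s, perl = TRUE))[[1]]
  if (length(m) == 0L) {
    # locate the first token that breaks the grammar for the error message
    ok <- regmatches(s, regexec("^A[0-9](B?)(G[0-9])?", s))[[1]]
    bad <- substr(s, nchar(ok[1]) + 1L, nchar(s))
    stop(sprintf("malformed Oxford glycan name '%s': cannot parse '%s'",
                 name, if (nzchar(bad)) bad else s), call. = FALSE)
  }
  antennae  <- as.integer(m[2])
  bisecting <- nzchar(m[3])
  galactose <- as.integer(m[4])
  neuac     <- if (nzchar(m[5])) as.integer(m[5]) else 0L
  # F may have matched in either position (lookahead branch or terminal)
  fuc <- lengths(gregexpr("F", s, fixed = TRUE))
  if (!grepl("F", s, fixed = TRUE)) fuc <- 0L
  if (fuc > 1L)
    stop(sprintf("malformed Oxford glycan name '%s': repeated 'F'", name),
         call. = FALSE)
  if (galactose > antennae)
    stop(sprintf("invalid glycan '%s': %d galactoses exceed %d antennae",
                 name, galactose, antennae), call. = FALSE)
  if (neuac > galactose)
    stop(sprintf("invalid glycan '%s': %d sialic acids exceed %d galactoses",
                 name, neuac, galactose), call. = FALSE)
  structure(list(
    hexnac    = 2L + antennae + as.integer(bisecting),
    hex       = 3L + galactose,
    fuc       = fuc,
    neuac     = neuac,
    bisecting = bisecting,
    antennae  = antennae,
    galactose = galactose
  ), class = "glycan_composition")
}

#' Canonical Oxford name of a composition
#'
#' @param comp A `glycan_composition` from [parse_oxford()].
#' @return A string such as `"A2BG0F"`; `F` always printed last.
#' @export
format_oxford <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  paste0("A", comp$antennae,
         if (comp$bisecting) "B" else "",
         "G", comp$galactose,
         if (comp$neuac > 0) paste0("S", comp$neuac) else "",
         if (comp$fuc > 0) "F" else "")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(sprintf("<glycan %s> HexNAc:%d Hex:%d Fuc:%d NeuAc:%d%s\n",
              format_oxford(x), x$hexnac, x$hex, x$fuc, x$neuac,
              if (x$bisecting) " (bisecting)" else ""))
  invisible(x)
}

#' Parse a channel-prefixed glycan feature label
#'
#' Feature labels tie a glycan to its antibody capture channel:
#' `G` is total IgG and `G1`..`G4` the IgG subclasses, e.g. `"G4.A2BG0F"`.
#' Whitespace after the dot is tolerated (`"G. A2BG0F"`).
#'
#' @param label String `<prefix>.<oxford-name>`.
#' @return List with `channel` (`"IgG"`, `"IgG1"`, ...), `prefix`,
#'   `glycan` (canonical Oxford name) and `composition`.
#' @examples
#' parse_channel_feature("G4.A2BG0F")
#' @export
parse_channel_feature <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  parts <- regmatches(label, regexec("^\\s*(G[0-9]?)\\.\\s*(\\S+)\\s*$", label))[[1]]
  if (length(parts) == 0L)
    stop(sprintf("malformed feature label '%s': expected '<prefix>.<glycan>'",
                 label), call. = FALSE)
  prefix <- parts[2]
  if (!prefix %in% names(CHANNELS))
    stop(sprintf("unknown channel prefix '%s' in '%s' (known: %s)",
                 prefix, label, paste(names(CHANNELS), collapse = ", ")),
         call. = FALSE)
  comp <- parse_oxford(parts[3])
  list(channel = unname(CHANNELS[prefix]), prefix = prefix,
       glycan = format_oxford(comp), composition = comp)
}

#' Monoisotopic neutral mass of a glycan composition
#'
#' Sum of glycosidic residue masses plus one water for the reducing end.
#'
#' @param comp A `glycan_composition`, or an Oxford name string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' neutral_mass("A2G0F")  # 1462.544438
#' @export
neutral_mass <- function(comp) {
  if (is.character(comp)) comp <- parse_oxford(comp)
  stopifnot(inherits(comp, "glycan_composition"))
  counts <- c(comp$hexnac, comp$hex, comp$fuc, comp$neuac)
  if (any(counts < 0)) stop("negative residue count", call. = FALSE)
  sum(counts * RESIDUE_MASS) + WATER_MASS
}

#' Theoretical m/z of a singly charged adduct
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param adduct One of `"M+H"`, `"M+Na"`, `"M+2Na-H"`.
#' @return m/z (charge 1).
#' @examples
#' adduct_mz(neutral_mass("A2G0F"), "M+Na")  # 1485.533656
#' @export
adduct_mz <- function(mass, adduct = c("M+H", "M+Na", "M+2Na-H")) {
  stopifnot(is.numeric(mass), all(mass > 0))
  if (!all(adduct %in% names(ADDUCT_MASS)))
    stop(sprintf("unknown adduct '%s' (known: %s)",
                 paste(setdiff(adduct, names(ADDUCT_MASS)), collapse = ", "),
                 paste(names(ADDUCT_MASS), collapse = ", ")), call. = FALSE)
  unname(mass + ADDUCT_MASS[adduct])
}

default_adduct <- function(comp) {
  # positive-mode MALDI: neutral glycans fly as [M+Na]+, sialylated ones
  # exchange the acidic proton and fly as [M+2Na-H]+
  if (comp$neuac > 0) "M+2Na-H" else "M+Na"
}

#' Build a theoretical-mass glycan panel
#'
#' A panel maps feature labels to the theoretical m/z used for peak picking.
#' Labels may be channel-prefixed (`"G1.A2G0F"`) or bare Oxford names.
#'
#' @param labels Character vector of labels.
#' @param adduct Per-entry adduct; `NULL` picks `M+Na` for neutral and
#'   `M+2Na-H` for sialylated glycans. Recycled if length 1.
#' @return Data frame of class `glycan_panel` with columns `label`,
#'   `channel`, `glycan`, `adduct`, `neutral_mass`, `theoretical_mz`.
#' @examples
#' glycan_panel(c("G.A2G0F", "G.A2G2S1"))
#' @export
glycan_panel <- function(labels, adduct = NULL) {
  stopifnot(is.character(labels), length(labels) >= 1L)
  rows <- lapply(seq_along(labels), function(i) {
    lab <- labels[i]
    if (grepl("\\.", lab)) {
      cf <- parse_channel_feature(lab)
      channel <- cf$channel; glycan <- cf$glycan; comp <- cf$composition
    } else {
      comp <- parse_oxford(lab)
      channel <- NA_character_; glycan <- format_oxford(comp)
    }
    add <- if (is.null(adduct)) default_adduct(comp)
           else if (length(adduct) == 1L) adduct else adduct[i]
    nm <- neutral_mass(comp)
    data.frame(label = lab, channel = channel, glycan = glycan,
               adduct = add, neutral_mass = nm,
               theoretical_mz = adduct_mz(nm, add),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  key <- paste(out$channel, out$glycan, out$adduct)
  if (anyDuplicated(key))
    stop("duplicate panel entries: ",
         paste(unique(out$label[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  stopifnot(all(out$theoretical_mz > 0))
  class(out) <- c("glycan_panel", "data.frame")
  out
}

#' Read / write a panel TSV
#'
#' The panel file has columns `label, channel, glycan, adduct,
#' theoretical_mz`; on read each row is re-validated against the parser and
#' the stored m/z checked against the recomputed value (1 mDa tolerance).
#'
#' @param path File path.
#' @return `read_panel` returns a `glycan_panel`.
#' @export
read_panel <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("label", "adduct", "theoretical_mz")
  if (!all(need %in% names(tab)))
    stop("panel file must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  panel <- glycan_panel(tab$label, adduct = tab$adduct)
  off <- abs(panel$theoretical_mz - tab$theoretical_mz)
  if (any(off > 1e-3))
    stop(sprintf("panel m/z mismatch for '%s': file %.6f vs computed %.6f",
                 tab$label[which.max(off)], tab$theoretical_mz[which.max(off)],
                 panel$theoretical_mz[which.max(off)]), call. = FALSE)
  panel
}

#' @rdname read_panel
#' @param panel A `glycan_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "glycan_panel"))
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pool of valid Oxford names
#'
#' Enumerates syntactically valid Oxford compositions (antennae 1--4,
#' all consistent galactose/sialic-acid counts, with and without bisecting
#' GlcNAc and core fucose) in a deterministic order. Used by the cohort
#' simulator to build arbitrarily wide per-channel panels.
#'
#' @param n Number of names wanted.
#' @return Character vector of `n` distinct Oxford names.
#' @export
oxford_name_pool <- function(n) {
  pool <- character(0)
  for (a in 2:4) for (b in c("", "B")) for (g in 0:a) for (s in 0:g)
    for (f in c("F", "")) {
      pool <- c(pool, paste0("A", a, b, "G", g,
                             if (s > 0) paste0("S", s) else "", f))
    }
  pool <- unique(pool)
  if (n > length(pool))
    stop(sprintf("only %d distinct Oxford names available (asked for %d)",
                 length(pool), n), call. = FALSE)
  pool[seq_len(n)]
}
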