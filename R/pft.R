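#' Taxon-to-PFT dictionary
#'
#' Maps pollen taxa to the plant functional types (PFTs) used for analog
#' matching. A taxon may be eligible for several PFTs (e.g. *Betula*, which
#' can behave as a boreal summergreen tree or as an arctic-alpine shrub
#' depending on the rest of the assemblage); ambiguity is resolved at
#' scoring time by the context rule of [taxa_to_pft()]. Per-taxon flags mark
#' arboreal habit, dwarf shrubs and vines -- the latter two are excluded
#' from arboreal-pollen (AP) sums.
#'
#' @param df data frame with columns `taxon`, `pfts` (comma-separated PFT
#'   names, empty = explicitly unassigned), `arboreal`, `dwarf_shrub`,
#'   `vine` (logical).
#' @return an object of class `pft_dictionary`.
#' @export
pft_dictionary <- function(df) {
  stopifnot(all(c("taxon", "pfts", "arboreal", "dwarf_shrub", "vine") %in% names(df)))
  df$taxon <- as.character(df$taxon)
  df$pfts <- as.character(df$pfts)
  for (fl in c("arboreal", "dwarf_shrub", "vine")) df[[fl]] <- as.logical(df[[fl]])
  if (any((df$dwarf_shrub | df$vine) & !df$arboreal))
    stop("dwarf-shrub and vine flags imply woody habit (arboreal = TRUE)")
  df$.key <- normalize_taxon(df$taxon)
  if (anyDuplicated(df$.key)) stop("duplicate taxon in dictionary")
  attr(df, "pft_names") <- sort(unique(unlist(strsplit(df$pfts[nzchar(df$pfts)], ","))))
  class(df) <- c("pft_dictionary", class(df))
  df
}

#' @rdname pft_dictionary
#' @param path delimited-text dictionary (columns as above; tab or comma).
#' @export
read_pft_dictionary <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  pft_dictionary(utils::read.table(path, header = TRUE, sep = sep,
                                   stringsAsFactors = FALSE))
}

#' @rdname pft_dictionary
#' @export
pft_names <- function(dict) attr(dict, "pft_names")

#' Synthetic 8-taxon / 5-PFT dictionary
#'
#' The fixture dictionary shipped with the package: four canopy trees, one
#' ambiguous tree/shrub taxon (*Betula*), one dwarf shrub and two herbs.
#' Column `productivity` is the relative pollen-productivity multiplier used
#' by the synthetic forward model (not part of the dictionary contract).
#'
#' @export
synthetic_pft_dictionary <- function() {
  d <- data.frame(
    taxon      = c("Pinus", "Picea", "Quercus", "Corylus", "Betula",
                   "Calluna", "Poaceae", "Artemisia"),
    pfts       = c("boreal_conifer", "boreal_conifer", "temperate_broadleaf",
                   "temperate_broadleaf", "boreal_summergreen,arctic_alpine",
                   "arctic_alpine", "steppe_grass", "steppe_grass"),
    arboreal   = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    dwarf_shrub = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    vine       = rep(FALSE, 8),
    productivity = c(4, 2, 2, 1.5, 3, 1, 1.5, 1),
    stringsAsFactors = FALSE)
  pft_dictionary(d)
}

pft_membership <- function(dict) {
  lapply(stats::setNames(strsplit(dict$pfts, ","), dict$.key),
         function(p) p[nzchar(p)])
}

#' Convert taxon percentages to PFT scores
#'
#' Biomisation-style affinity scoring: each taxon with percentage p above
#' the threshold theta contributes `sqrt(p - theta)` to its PFT. Taxa
#' eligible for several PFTs are resolved by the context rule: the taxon is
#' assigned wholly to the eligible PFT with the larger score computed from
#' the other taxa; exact ties are split equally.
#'
#' @param perc named numeric vector of taxon percentages (one sample), or a
#'   matrix with taxa as columns (one row per sample).
#' @param dict a [pft_dictionary()].
#' @param theta threshold in percentage points (default 0.5, standard
#'   biomisation practice).
#' @return for a vector input, a list with `raw` and `norm` (scores summing
#'   to 1) named by PFT; for a matrix input, the matrix of normalized score
#'   vectors (raw scores in attribute `"raw"`).
#' @export
taxa_to_pft <- function(perc, dict, theta = 0.5) {
  if (nrow(dict) == 0) stop("empty PFT dictionary")
  if (is.matrix(perc) || is.data.frame(perc)) {
    perc <- as.matrix(perc)
    out <- t(apply(perc, 1, function(p) {
      r <- taxa_to_pft(p, dict, theta)
      c(r$norm, r$raw)
    }))
    npft <- length(pft_names(dict))
    norm <- out[, seq_len(npft), drop = FALSE]
    raw <- out[, npft + seq_len(npft), drop = FALSE]
    colnames(norm) <- colnames(raw) <- pft_names(dict)
    rownames(norm) <- rownames(raw) <- rownames(perc)
    attr(norm, "raw") <- raw
    return(norm)
  }
  pfts <- pft_names(dict)
  member <- pft_membership(dict)
  key <- normalize_taxon(names(perc))
  contrib <- sqrt(pmax(0, perc - theta))
  eligible <- member[key]
  nelig <- vapply(eligible, length, 0L)
  known <- !vapply(eligible, is.null, TRUE)
  score <- stats::setNames(numeric(length(pfts)), pfts)
  # pass 1: unambiguous taxa
  for (i in which(known & nelig == 1 & contrib > 0))
    score[eligible[[i]]] <- score[eligible[[i]]] + contrib[i]
  base <- score
  # pass 2: ambiguous taxa, resolved against the scores of the other taxa
  for (i in which(known & nelig > 1 & contrib > 0)) {
    cand <- eligible[[i]]
    other <- base[cand]
    best <- cand[other == max(other)]
    score[best] <- score[best] + contrib[i] / length(best)
  }
  tot <- sum(score)
  list(raw = score, norm = if (tot > 0) score / tot else score)
}

#' Arboreal-pollen percentage
#'
#' Sum of the percentages of taxa flagged arboreal, excluding dwarf shrubs
#' and vines. Taxa absent from the dictionary count as non-arboreal.
#'
#' @inheritParams taxa_to_pft
#' @return percentage in `[0, 100]` (vector if `perc` is a matrix).
#' @export
ap_percentage <- function(perc, dict) {
  ap_taxa <- dict$.key[dict$arboreal & !dict$dwarf_shrub & !dict$vine]
  if (is.matrix(perc) || is.data.frame(perc)) {
    perc <- as.matrix(perc)
    sel <- normalize_taxon(colnames(perc)) %in% ap_taxa
    return(rowSums(perc[, sel, drop = FALSE]))
  }
  key <- normalize_taxon(names(perc))
  unknown <- setdiff(key, dict$.key)
  if (length(unknown))
    message("taxa not in dictionary treated as non-arboreal: ",
            paste(unknown, collapse = ", "))
  sum(perc[key %in% ap_taxa])
}
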