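#' Parse a consensus phosphorylation motif pattern
#'
#' Patterns use the conventional dash notation, e.g. `"R-x-x-S/T"`
#' (an arginine three residues upstream of a serine or threonine acceptor)
#' or `"S/T-P"` (proline-directed). Each dash-separated token is an allowed
#' residue set (`/`-separated one-letter codes); `x` is a fully degenerate
#' position and contributes no constraint. The phosphoacceptor (offset 0) is
#' the first token whose allowed set is contained in {S, T, Y}.
#'
#' @param kinase kinase identifier.
#' @param pattern pattern string.
#' @return `kpnet_motif`: list with `$kinase`, `$pattern`, `$offsets` (named
#'   list: character offset -> allowed residue vector), `$acceptor` (allowed
#'   residues at offset 0).
#' @export
parse_motif <- function(kinase, pattern) {
  tokens <- strsplit(toupper(pattern), "-", fixed = TRUE)[[1]]
  if (length(tokens) == 0) {
    stop_kpnet("empty motif pattern", class = "kpnet_format_error")
  }
  sets <- lapply(tokens, function(tk) {
    if (tk %in% c("X", "")) return(NULL)
    strsplit(tk, "/", fixed = TRUE)[[1]]
  })
  acceptor_idx <- NA_integer_
  for (i in seq_along(sets)) {
    if (!is.null(sets[[i]]) && all(sets[[i]] %in% c("S", "T", "Y"))) {
      acceptor_idx <- i
      break
    }
  }
  if (is.na(acceptor_idx)) {
    stop_kpnet("motif '%s' has no phosphoacceptor position (S/T/Y)", pattern,
               class = "kpnet_format_error")
  }
  offsets <- list()
  for (i in seq_along(sets)) {
    if (is.null(sets[[i]])) next
    offsets[[as.character(i - acceptor_idx)]] <- sets[[i]]
  }
  structure(list(kinase = kinase, pattern = pattern, offsets = offsets,
                 acceptor = sets[[acceptor_idx]]), class = "kpnet_motif")
}

#' Read a kinase consensus-motif table
#'
#' TSV with columns `kinase`, `pattern`. A kinase may appear on several rows
#' (its motifs combine as a logical OR).
#'
#' @param path path to the TSV.
#' @return list of `kpnet_motif` objects.
#' @export
read_motifs <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("kinase", "pattern") %in% names(tab))) {
    stop_kpnet("motif table must have columns kinase, pattern",
               class = "kpnet_format_error")
  }
  mapply(parse_motif, tab$kinase, tab$pattern,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Match a motif against a phosphosite in a protein sequence
#'
#' `TRUE` iff the residue at every constrained offset of the motif (relative
#' to `position`, the phosphoacceptor) matches its allowed set. A constrained
#' offset falling outside the sequence fails the match (boundary-fail
#' convention).
#'
#' @param motif a `kpnet_motif` from [parse_motif()].
#' @param sequence protein sequence, one-letter codes.
#' @param position 1-based position of the phosphoacceptor.
#' @return logical.
#' @export
match_motif <- function(motif, sequence, position) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (position < 1 || position > n) {
    stop_kpnet("position %d outside sequence of length %d", position, n,
               class = "kpnet_argument_error")
  }
  for (off in names(motif$offsets)) {
    pos <- position + as.integer(off)
    if (pos < 1 || pos > n) return(FALSE)
    if (!substr(sequence, pos, pos) %in% motif$offsets[[off]]) return(FALSE)
  }
  TRUE
}

#' Predict kinase-substrate interactions from motifs and dynamic phosphosites
#'
#' Candidate edges connect every kinase whose consensus motif matches a
#' dynamic phosphosite to that site's protein; retained edges are the
#' candidates that occur in the gold-standard network (its collapsed arcs).
#'
#' @param network the gold-standard [kpnet_network()].
#' @param motifs list of `kpnet_motif` objects (see [parse_motif()],
#'   [read_motifs()]); several motifs per kinase act as a logical OR.
#' @param phosphosites data.frame with columns `protein`, `position`,
#'   `residue`, `dynamic` (logical or 0/1).
#' @param sequences named character vector of protein sequences for the
#'   phosphosite proteins.
#' @return `kpnet_prediction`: list with `$candidates`, `$retained`
#'   (data.frames kinase, substrate), `$summary` (retained edges, distinct
#'   kinases, distinct substrates).
#' @export
predict_interactions <- function(network, motifs, phosphosites, sequences) {
  if (length(motifs) == 0) {
    stop_kpnet("no motifs supplied", class = "kpnet_argument_error")
  }
  ph <- as.data.frame(phosphosites, stringsAsFactors = FALSE)
  need <- c("protein", "position", "residue", "dynamic")
  if (!all(need %in% names(ph))) {
    stop_kpnet("phosphosite table must have columns %s",
               paste(need, collapse = ", "), class = "kpnet_format_error")
  }
  ph$dynamic <- as.logical(as.numeric(ph$dynamic))
  dyn <- ph[ph$dynamic & ph$protein %in% names(sequences), , drop = FALSE]
  cand <- list()
  for (i in seq_len(nrow(dyn))) {
    prot <- dyn$protein[i]
    pos <- as.integer(dyn$position[i])
    for (mo in motifs) {
      if (match_motif(mo, sequences[[prot]], pos)) {
        cand[[length(cand) + 1L]] <-
          data.frame(kinase = mo$kinase, substrate = prot,
                     stringsAsFactors = FALSE)
      }
    }
  }
  candidates <- if (length(cand) == 0) {
    data.frame(kinase = character(), substrate = character(),
               stringsAsFactors = FALSE)
  } else {
    unique(do.call(rbind, cand))
  }
  gold <- arc_key(network$edges$source, network$edges$target)
  keep <- arc_key(candidates$kinase, candidates$substrate) %in% gold
  retained <- candidates[keep, , drop = FALSE]
  retained <- retained[order(retained$kinase, retained$substrate), ,
                       drop = FALSE]
  rownames(retained) <- NULL
  structure(list(
    candidates = candidates, retained = retained,
    summary = c(edges = nrow(retained),
                kinases = length(unique(retained$kinase)),
                substrates = length(unique(retained$substrate)))),
    class = "kpnet_prediction")
}

#' @export
print.kpnet_prediction <- function(x, ...) {
  cat(sprintf(
    "prediction: %d retained edges (%d kinases, %d substrates; %d candidates)\n",
    x$summary[["edges"]], x$summary[["kinases"]], x$summary[["substrates"]],
    nrow(x$candidates)))
  invisible(x)
}
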