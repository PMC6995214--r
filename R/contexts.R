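#' The 96 trinucleotide mutation contexts
#'
#' Somatic single-base substitutions are described on the pyrimidine strand:
#' six substitution types (C>A, C>G, C>T, T>A, T>C, T>G), each observed in 16
#' combinations of the 5' and 3' flanking bases, giving the standard 96
#' context bins used for mutational-signature analysis.
#'
#' @return Character vector of length 96 with labels such as `"A[C>A]A"`,
#'   ordered by substitution type, then 5' flank, then 3' flank.
#' @export
#' @examples
#' head(sbs_contexts())
sbs_contexts <- function() {
  subs <- substitution_types()
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(up, down) {
      paste0(up, "[", s, "]", down)
    })))
  }), use.names = FALSE)
}

#' @rdname sbs_contexts
#' @export
substitution_types <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

revcomp_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

#' Pyrimidine-strand normalization of a substitution and its context
#'
#' Substitutions recorded with a purine reference base (A or G) are
#' reverse-complemented so that every mutation is expressed with a C or T
#' reference; the flanking bases are complemented and swapped accordingly.
#'
#' @param ref,alt Reference and alternate single bases (vectors).
#' @param up,down 5' and 3' flanking bases on the same strand as `ref`.
#' @return Tibble with columns `substitution` (one of the six pyrimidine
#'   types), `context` (96-bin label) and `is_transition`.
#' @export
#' @examples
#' normalize_substitution("G", "T", "T", "T") # -> A[C>A]A
normalize_substitution <- function(ref, alt, up, down) {
  stopifnot(length(ref) == length(alt), length(up) == length(ref),
            length(down) == length(ref))
  purine <- ref %in% c("A", "G")
  nref <- ifelse(purine, revcomp_base(ref), ref)
  nalt <- ifelse(purine, revcomp_base(alt), alt)
  nup <- ifelse(purine, revcomp_base(down), up)
  ndown <- ifelse(purine, revcomp_base(up), down)
  sub <- paste0(nref, ">", nalt)
  ok <- sub %in% substitution_types() &
    nup %in% c("A", "C", "G", "T") & ndown %in% c("A", "C", "G", "T")
  ctx <- ifelse(ok, paste0(nup, "[", sub, "]", ndown), NA_character_)
  tibble(
    substitution = ifelse(ok, sub, NA_character_),
    context = ctx,
    is_transition = ifelse(ok, sub %in% c("C>T", "T>C"), NA)
  )
}

#' Decompose a 96-context label into its parts
#'
#' @param context Character vector of labels such as `"A[C>T]G"`.
#' @return Tibble with columns `up`, `ref`, `alt`, `down`, `substitution`.
#' @export
parse_context <- function(context) {
  m <- stringr::str_match(context, "^([ACGT])\\[([CT])>([ACGT])\\]([ACGT])$")
  bad <- !is.na(context) & is.na(m[, 1])
  if (any(bad)) {
    abort(paste0("malformed context label(s): ",
                 paste(unique(context[bad]), collapse = ", ")))
  }
  tibble(
    up = m[, 2], ref = m[, 3], alt = m[, 4], down = m[, 5],
    substitution = paste0(m[, 3], ">", m[, 4])
  )
}
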