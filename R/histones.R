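# mature (Met-cleaved) human canonical H3.1; histone-field numbering
H3_REFERENCE <- paste0(
  "ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHR",
  "YRPGTVALREIRRYQKSTELLIRKLPFQRLVREIAQDFKT",
  "DLRFQSSAVMALQEACEAYLVGLFEDTNLCAIHAKRVTIM",
  "PKDIQLARRIRGERA"
)

#' Region annotation of a canonical histone H3 reference
#'
#' Coordinates (1-based, inclusive) are on the ungapped reference sequence
#' and are mapped to alignment columns when a query is classified. The
#' defaults follow standard H3 fold annotation on the mature human H3.1
#' sequence: N-terminal tail 1-44, alpha-1 helix 63-77 with the conserved
#' glutamine at 68, loop 1 78-84, histone fold domain 63-131.
#'
#' @param reference ungapped canonical H3 amino-acid string.
#' @param tail,alpha1,loop1,fold integer length-2 vectors `c(start, end)`.
#' @param glutamine_col reference position of the conserved alpha-1
#'   glutamine (must lie inside `alpha1` and be `Q` in the reference).
#' @return an object of class `histone_regions`.
#' @export
histone_regions <- function(reference = H3_REFERENCE,
                            tail = c(1L, 44L), alpha1 = c(63L, 77L),
                            loop1 = c(78L, 84L), fold = c(63L, 131L),
                            glutamine_col = 68L) {
  n <- nchar(reference)
  for (iv in list(tail = tail, alpha1 = alpha1, loop1 = loop1, fold = fold)) {
    if (length(iv) != 2L || iv[1] < 1L || iv[2] > n || iv[1] > iv[2]) {
      stop("region interval out of reference bounds [1, ", n, "]",
           call. = FALSE)
    }
  }
  if (glutamine_col < alpha1[1] || glutamine_col > alpha1[2]) {
    stop("glutamine column must lie inside the alpha-1 helix", call. = FALSE)
  }
  if (substr(reference, glutamine_col, glutamine_col) != "Q") {
    stop("reference residue at the glutamine column is not Q", call. = FALSE)
  }
  structure(
    list(reference = reference, tail = as.integer(tail),
         alpha1 = as.integer(alpha1), loop1 = as.integer(loop1),
         fold = as.integer(fold), glutamine_col = as.integer(glutamine_col)),
    class = "histone_regions"
  )
}

#' Classify a histone H3-like sequence as caH3/H3.3, cenH3 or H3V candidate
#'
#' Operates on a pairwise alignment of the query against the canonical
#' reference. Four criteria are computed: `loop1_insertion` (>= 1
#' alignment column inside loop 1 where the canonical row has a gap and
#' the query does not), `tail_divergent` (identity over the N-terminal
#' tail below `tail_identity_max`), `q_absent` (query residue at the
#' conserved alpha-1 glutamine column is not Q), and `fold_divergent`
#' (identity over the histone fold domain below `fold_identity_max`).
#'
#' Decision rules: `cenH3_candidate` iff all four criteria hold (or at
#' least 3 with `require_all = FALSE`); `H3V_candidate` iff
#' `tail_divergent` and `q_absent` without a loop-1 insertion;
#' `caH3/H3.3` iff none of the criteria holds; otherwise `unclassified`.
#' The outcomes are mutually exclusive and exhaustive.
#'
#' @param query aligned query amino-acid string (gaps `-`).
#' @param canonical aligned canonical row, same length as `query`; its
#'   ungapped sequence must equal `regions$reference`.
#' @param regions a [histone_regions()].
#' @param tail_identity_max,fold_identity_max divergence thresholds
#'   (identity strictly below => divergent); defaults 0.5 and 0.75.
#' @param require_all require all four cenH3 criteria (default) or any 3.
#' @return list with `class` (one of `"caH3/H3.3"`, `"cenH3_candidate"`,
#'   `"H3V_candidate"`, `"unclassified"`), `criteria` (named logical
#'   vector), `tail_identity`, `fold_identity`.
#' @export
classify_histone <- function(query, canonical, regions = histone_regions(),
                             tail_identity_max = 0.5,
                             fold_identity_max = 0.75,
                             require_all = TRUE) {
  stopifnot(inherits(regions, "histone_regions"))
  qv <- strsplit(toupper(query), "")[[1]]
  cv <- strsplit(toupper(canonical), "")[[1]]
  if (length(qv) != length(cv)) {
    stop("query and canonical rows must be aligned (equal length)",
         call. = FALSE)
  }
  if (gsub("-", "", canonical, fixed = TRUE) != regions$reference) {
    stop("ungapped canonical row does not match regions$reference",
         call. = FALSE)
  }
  refcols <- which(cv != "-")              # alignment column of ref pos i
  if (max(regions$fold) > length(refcols)) {
    stop("alignment does not cover the histone fold domain", call. = FALSE)
  }
  region_identity <- function(iv) {
    cols <- refcols[iv[1]:iv[2]]
    mean(qv[cols] == cv[cols])
  }
  l1_span <- refcols[regions$loop1]
  l1_cols <- seq(l1_span[1], l1_span[2])
  criteria <- c(
    loop1_insertion = any(cv[l1_cols] == "-" & qv[l1_cols] != "-"),
    tail_divergent = region_identity(regions$tail) < tail_identity_max,
    q_absent = qv[refcols[regions$glutamine_col]] != "Q",
    fold_divergent = region_identity(regions$fold) < fold_identity_max
  )
  cen_ok <- if (require_all) all(criteria) else sum(criteria) >= 3L
  cls <- if (cen_ok && criteria[["loop1_insertion"]]) {
    "cenH3_candidate"
  } else if (criteria[["tail_divergent"]] && criteria[["q_absent"]] &&
             !criteria[["loop1_insertion"]]) {
    "H3V_candidate"
  } else if (!any(criteria)) {
    "caH3/H3.3"
  } else {
    "unclassified"
  }
  list(class = cls, criteria = criteria,
       tail_identity = region_identity(regions$tail),
       fold_identity = region_identity(regions$fold))
}
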