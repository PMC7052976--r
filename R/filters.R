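AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing residues among comparable alignment columns,
#' with pairwise deletion: columns where either sequence has a gap (`-`)
#' or an ambiguous residue (`X`) are excluded from the denominator (the
#' default p-distance behavior of MEGA-style tools).
#'
#' @param a,b aligned amino-acid strings of equal length.
#' @return numeric in `[0, 1]`.
#' @examples
#' p_distance("AAAA", "AAAT")   # 0.25
#' p_distance("AA-CG", "AATCG") # 0: the gapped column is skipped
#' @export
p_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  comparable <- !(av %in% c("-", "X")) & !(bv %in% c("-", "X"))
  if (!any(comparable)) {
    stop("no comparable (non-gap, non-ambiguous) columns", call. = FALSE)
  }
  mean(av[comparable] != bv[comparable])
}

#' Taxonomic best-hit decontamination call for one query
#'
#' Implements the transcriptome decontamination rule: sort the query's hits
#' by descending bitscore (ties broken by ascending E-value, then subject
#' id), keep the top `top_n`, and exclude the query as a contaminant iff
#' the bacterial fraction among the retained hits strictly exceeds
#' `bacterial_frac`. The denominator is the number of hits actually used
#' (fewer than `top_n` hits may be available). A query with no hits is
#' kept.
#'
#' @param hits data frame with columns `subject`, `class` (values
#'   `"bacterial"`, `"eukaryotic"`, `"other"`), `bitscore`, `evalue`; may
#'   have zero rows.
#' @param top_n number of best hits retained (default 20).
#' @param bacterial_frac exclusion threshold on the bacterial fraction
#'   (default 0.6; strict inequality).
#' @return list with `decision` (`"keep"` or `"exclude"`), `fraction`
#'   (bacterial fraction among used hits; `NA` with no hits), `n_used`.
#' @export
classify_contaminant <- function(hits, top_n = 20L, bacterial_frac = 0.6) {
  stopifnot(is.data.frame(hits))
  if (!nrow(hits)) {
    return(list(decision = "keep", fraction = NA_real_, n_used = 0L))
  }
  need <- c("subject", "class", "bitscore", "evalue")
  if (!all(need %in% names(hits))) {
    stop("hit table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(-hits$bitscore, hits$evalue, hits$subject)
  top <- hits[utils::head(ord, top_n), , drop = FALSE]
  frac <- mean(top$class == "bacterial")
  list(decision = if (frac > bacterial_frac) "exclude" else "keep",
       fraction = frac, n_used = nrow(top))
}

#' Scan a transcript 5' end for a splice-leader suffix
#'
#' Euglenozoan mRNAs carry a splice leader (SL) trans-spliced onto their 5'
#' end; finding the 3'-terminal part of the SL at the start of a transcript
#' evidences host (not contaminant) origin. The scan looks for the longest
#' exact match of an SL suffix of length >= `min_len` starting within the
#' first `window` nt of the transcript, on the given strand and on the
#' reverse complement (so the 5' end of either strand qualifies).
#'
#' @param transcript nucleotide string.
#' @param sl splice-leader nucleotide string.
#' @param min_len minimal SL suffix length (default 12 nt).
#' @param window the match must start within this many nt of the 5' end
#'   (default 30).
#' @return list with `found`, `length` (matched suffix length, 0 if none),
#'   `position` (1-based match start, `NA` if none), `strand` (`"+"`,
#'   `"-"`, or `NA`).
#' @export
sl_scan <- function(transcript, sl, min_len = 12L, window = 30L) {
  stopifnot(nzchar(transcript), nzchar(sl))
  if (min_len > nchar(sl)) {
    stop("min_len (", min_len, ") exceeds SL length (", nchar(sl), ")",
         call. = FALSE)
  }
  transcript <- toupper(transcript)
  sl <- toupper(sl)
  strands <- c("+" = transcript, "-" = revcomp(transcript))
  for (L in seq(nchar(sl), min_len)) {         # longest suffix first
    suffix <- substr(sl, nchar(sl) - L + 1L, nchar(sl))
    for (s in names(strands)) {
      pos <- regexpr(suffix, strands[[s]], fixed = TRUE)
      if (pos > 0L && pos <= window) {
        return(list(found = TRUE, length = L, position = as.integer(pos),
                    strand = s))
      }
    }
  }
  list(found = FALSE, length = 0L, position = NA_integer_,
       strand = NA_character_)
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTUacgtu", "TGCAAtgcaa", x), "")[[1]]),
        collapse = "")
}

#' Define a homolog acceptance profile
#'
#' Bundles the thresholds of a rule-based divergent-homolog filter:
#' E-value ceilings per search type, a p-distance ceiling, and optional
#' splice-leader and domain-extension requirements.
#'
#' @param name profile name.
#' @param blast_evalue_max,hmm_evalue_max E-value ceilings (`NULL` when the
#'   search type is not used).
#' @param pdist_max p-distance ceiling to the reference (`NULL` to skip).
#' @param require_sl require a splice-leader match on the transcript.
#' @param require_domain_extension require hit coordinates extending beyond
#'   the predicted borders of a conserved domain (guards against matching a
#'   widespread domain shared with unrelated proteins).
#' @return an object of class `filter_profile`.
#' @export
filter_profile <- function(name, blast_evalue_max = NULL,
                           hmm_evalue_max = NULL, pdist_max = NULL,
                           require_sl = FALSE,
                           require_domain_extension = FALSE) {
  for (th in list(blast_evalue_max, hmm_evalue_max, pdist_max)) {
    if (!is.null(th) && th <= 0) {
      stop("thresholds must be > 0 where set", call. = FALSE)
    }
  }
  structure(
    list(name = name, blast_evalue_max = blast_evalue_max,
         hmm_evalue_max = hmm_evalue_max, pdist_max = pdist_max,
         require_sl = isTRUE(require_sl),
         require_domain_extension = isTRUE(require_domain_extension)),
    class = "filter_profile"
  )
}

#' Built-in homolog acceptance profiles
#'
#' Presets mirroring the published screens: `trypanothione` (BLAST E <=
#' 1e-20, p-distance <= 0.7; the splice-leader check is enabled per call
#' for transcriptomic data), `prerc` (pre-replication complex: BLAST E <=
#' 1e-20, HMM E <= 1e-5, p-distance <= 0.75), `kkt` (kinetoplastid
#' kinetochore proteins: HMM E <= 1e-5, p-distance <= 0.8,
#' domain-extension required), and `kkip7` (BLAST E <= 1e-100, p-distance
#' <= 0.65).
#'
#' @return named list of [filter_profile()] objects.
#' @export
filter_presets <- function() {
  list(
    trypanothione = filter_profile("trypanothione",
                                   blast_evalue_max = 1e-20,
                                   pdist_max = 0.7),
    prerc = filter_profile("prerc", blast_evalue_max = 1e-20,
                           hmm_evalue_max = 1e-5, pdist_max = 0.75),
    kkt = filter_profile("kkt", hmm_evalue_max = 1e-5, pdist_max = 0.8,
                         require_domain_extension = TRUE),
    kkip7 = filter_profile("kkip7", blast_evalue_max = 1e-100,
                           pdist_max = 0.65)
  )
}

#' Accept or reject a candidate homolog against a profile
#'
#' A candidate is accepted iff every enabled rule passes: E-value at or
#' below the ceiling for its search type; p-distance at or below
#' `pdist_max`; a splice-leader match when required; and, when required,
#' hit coordinates extending beyond the predicted domain borders
#' (`hit_start < domain_start` or `hit_end > domain_end`). Each rule's
#' outcome is reported.
#'
#' @param candidate list with fields `evalue`, `search_type` (`"blast"` or
#'   `"hmm"`), and — as the profile demands — `pdist`, `sl_found`,
#'   `hit_start`, `hit_end`, `domain_start`, `domain_end`.
#' @param profile a [filter_profile()].
#' @return list with `decision` (`"accept"`/`"reject"`) and `rules`
#'   (named logical vector of enabled-rule outcomes).
#' @export
filter_homolog_hit <- function(candidate, profile) {
  stopifnot(inherits(profile, "filter_profile"), is.list(candidate))
  getf <- function(field, rule) {
    if (is.null(candidate[[field]]) || is.na(candidate[[field]])) {
      stop("candidate is missing field '", field, "' required by rule '",
           rule, "'", call. = FALSE)
    }
    candidate[[field]]
  }
  rules <- logical(0)
  st <- getf("search_type", "evalue")
  if (!st %in% c("blast", "hmm")) {
    stop("search_type must be 'blast' or 'hmm'", call. = FALSE)
  }
  thr <- if (st == "blast") profile$blast_evalue_max else profile$hmm_evalue_max
  if (is.null(thr)) {
    stop("profile '", profile$name, "' has no E-value threshold for ",
         st, " searches", call. = FALSE)
  }
  rules["evalue"] <- getf("evalue", "evalue") <= thr
  if (!is.null(profile$pdist_max)) {
    rules["pdist"] <- getf("pdist", "pdist") <= profile$pdist_max
  }
  if (profile$require_sl) {
    rules["sl"] <- isTRUE(getf("sl_found", "sl"))
  }
  if (profile$require_domain_extension) {
    hs <- getf("hit_start", "domain_extension")
    he <- getf("hit_end", "domain_extension")
    ds <- getf("domain_start", "domain_extension")
    de <- getf("domain_end", "domain_extension")
    rules["domain_extension"] <- (hs < ds) || (he > de)
  }
  list(decision = if (all(rules)) "accept" else "reject", rules = rules)
}
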