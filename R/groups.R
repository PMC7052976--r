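#' Define a species group for group-level presence calls
#'
#' A feature is called present in a group when it is present in at least
#' `min_present` member species. The comparative analyses this mirrors use
#' `min_present = 2` for most clades and 1 for small groups such as
#' Prokinetoplastina.
#'
#' @param name group name.
#' @param members character vector of species ids.
#' @param min_present minimum number of member species in which a feature
#'   must be present (>= 1, <= number of members).
#' @return an object of class `species_group`.
#' @export
species_group <- function(name, members, min_present = 2L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  members <- unique(as.character(members))
  stopifnot(length(members) >= 1L)
  min_present <- as.integer(min_present)
  if (min_present < 1L || min_present > length(members)) {
    stop("min_present must be in [1, ", length(members), "] for group '",
         name, "'", call. = FALSE)
  }
  structure(list(name = name, members = members, min_present = min_present),
            class = "species_group")
}

#' Per-species unique feature counts
#'
#' The number of unique KO identifiers per species is the repertoire-size
#' statistic used as a proxy for metabolic versatility.
#'
#' @param pm a [presence_matrix()].
#' @return named integer vector over species.
#' @export
unique_ko_counts <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  counts <- rowSums(pm$matrix)
  storage.mode(counts) <- "integer"
  counts
}

#' Group-level presence matrix
#'
#' Derives a group x feature binary matrix from species-level presence:
#' `cell(g, k) = 1` iff the feature is present in at least
#' `g$min_present` member species.
#'
#' @param pm a [presence_matrix()].
#' @param groups a list of [species_group()] objects.
#' @param allow_overlap permit groups sharing species (default errors).
#' @return a `group_matrix`: binary integer matrix (groups x features) with
#'   the group definitions in attribute `"groups"`.
#' @export
group_presence <- function(pm, groups, allow_overlap = FALSE) {
  stopifnot(inherits(pm, "presence_matrix"), length(groups) >= 1L)
  if (inherits(groups, "species_group")) groups <- list(groups)
  nm <- vapply(groups, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate group names", call. = FALSE)
  all_members <- unlist(lapply(groups, `[[`, "members"))
  missing <- setdiff(all_members, pm$species)
  if (length(missing)) {
    stop("group members not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!allow_overlap && anyDuplicated(all_members)) {
    dup <- unique(all_members[duplicated(all_members)])
    stop("overlapping groups (set allow_overlap = TRUE to permit): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  gm <- do.call(rbind, lapply(groups, function(g) {
    as.integer(colSums(pm$matrix[g$members, , drop = FALSE]) >= g$min_present)
  }))
  dimnames(gm) <- list(nm, pm$features)
  structure(gm, class = c("group_matrix", class(gm)), groups = groups)
}

#' Exclusive intersections of group presence (UpSet-style)
#'
#' Each feature present in at least one group is assigned to exactly one
#' subset: the exact set of groups where it is present. Features absent
#' everywhere contribute nowhere, so subset counts sum to the number of
#' features present in >= 1 group.
#'
#' @param gm a `group_matrix` from [group_presence()].
#' @return data frame with columns `subset` (group names joined by `&`),
#'   `degree` and `count`, sorted by decreasing count then subset name;
#'   per-subset feature ids are in the `"features"` attribute (a named
#'   list).
#' @export
exclusive_intersections <- function(gm) {
  stopifnot(inherits(gm, "group_matrix"))
  groups <- rownames(gm)
  present <- colSums(gm) > 0L
  feats <- colnames(gm)[present]
  if (!length(feats)) {
    res <- data.frame(subset = character(0), degree = integer(0),
                      count = integer(0))
    attr(res, "features") <- list()
    return(res)
  }
  pattern <- apply(gm[, feats, drop = FALSE] == 1L, 2L, function(col) {
    paste(groups[col], collapse = "&")
  })
  split_feats <- split(feats, pattern)
  res <- data.frame(subset = names(split_feats),
                    degree = lengths(strsplit(names(split_feats), "&",
                                              fixed = TRUE)),
                    count = lengths(split_feats),
                    stringsAsFactors = FALSE)
  ord <- order(-res$count, res$subset)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "features") <- split_feats[res$subset]
  res
}

#' Screen for convergent losses shared by two lineages
#'
#' Returns the features absent from every species of both target groups
#' while present in at least `min_background` background species — the rule
#' used to detect losses shared, e.g., by kinetoplastids and ciliates while
#' the feature is retained by other free-living heterotrophic protists.
#'
#' @param pm a [presence_matrix()].
#' @param target_groups list of exactly two [species_group()] objects (or
#'   character vectors of species ids).
#' @param background_species character vector of background species ids,
#'   disjoint from the targets.
#' @param min_background minimum background species carrying the feature
#'   (default 3).
#' @return character vector of feature ids.
#' @export
shared_loss_screen <- function(pm, target_groups, background_species,
                               min_background = 3L) {
  stopifnot(inherits(pm, "presence_matrix"), length(target_groups) == 2L)
  members <- lapply(target_groups, function(g) {
    if (inherits(g, "species_group")) g$members else as.character(g)
  })
  targets <- unique(unlist(members))
  background_species <- unique(as.character(background_species))
  if (!length(background_species)) {
    stop("background species set is empty", call. = FALSE)
  }
  overlap <- intersect(targets, background_species)
  if (length(overlap)) {
    stop("background overlaps target groups: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(c(targets, background_species), pm$species)
  if (length(missing)) {
    stop("species not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  absent_targets <- colSums(pm$matrix[targets, , drop = FALSE]) == 0L
  bg_present <- colSums(pm$matrix[background_species, , drop = FALSE])
  pm$features[absent_targets & bg_present >= min_background]
}

#' Compare repertoire sizes between two species sets (unpaired t test)
#'
#' Two-sided unpaired t test on per-species unique-KO counts, with Student's
#' pooled-variance test as the default (the classical reading of "unpaired
#' t test") and Welch's test available by flag.
#'
#' @param counts_a,counts_b numeric vectors (n >= 2 each).
#' @param method `"student"` (pooled variance, default) or `"welch"`.
#' @param alpha significance level; the returned CI has level `1 - alpha`.
#' @return list with `t`, `df`, `p`, `ci` (CI for mean(a) - mean(b)),
#'   `method`.
#' @export
compare_versatility <- function(counts_a, counts_b,
                                method = c("student", "welch"),
                                alpha = 0.05) {
  method <- match.arg(method)
  counts_a <- as.numeric(counts_a); counts_b <- as.numeric(counts_b)
  if (length(counts_a) < 2L || length(counts_b) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  n1 <- length(counts_a); n2 <- length(counts_b)
  d <- mean(counts_a) - mean(counts_b)
  if (stats::var(counts_a) == 0 && stats::var(counts_b) == 0) {
    # degenerate: t.test refuses essentially-constant data
    df <- if (method == "student") n1 + n2 - 2L else NA_real_
    if (d == 0) {
      return(list(t = 0, df = df, p = 1, ci = c(0, 0), method = method))
    }
    return(list(t = sign(d) * Inf, df = df, p = 0, ci = c(d, d),
                method = method))
  }
  tt <- stats::t.test(counts_a, counts_b, var.equal = (method == "student"),
                      conf.level = 1 - alpha)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, ci = unname(tt$conf.int), method = method)
}
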