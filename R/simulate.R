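EUGLENOZOA_NEWICK <- paste0(
  "(Ngru,((Rcos,(Egra,Egym)N1)N2,((Hpha,(Rhum,Sspe)N3)N4,",
  "((Perk,(PhF6,PhM4)N5)N6,((Ndes,Ahoy)N7,(Tbor,(Bsal,(Pcon,((Lmaj,Lpyr)N8,",
  "(Tbru,Tgra)N9)N10)N11)N12)N13)N14)N15)N16)N17)N18;"
)

#' The 19-taxon euglenozoan study tree
#'
#' Hand-encoded rooted topology of the 19-species comparative dataset
#' (18 euglenozoans plus the heterolobosean outgroup *Naegleria gruberi*,
#' abbreviated species ids), with internal nodes labelled so that `N15` is
#' the kinetoplastid crown, `N14` the node after the Prokinetoplastina
#' split, `N13` the node after the Neobodonida split, and `N11` the
#' trypanosomatid crown. Branch lengths are omitted (topology only).
#'
#' @return a `rooted_tree`.
#' @seealso [euglenozoa_sources()], [euglenozoa_groups()]
#' @export
euglenozoa_tree <- function() {
  read_newick(EUGLENOZOA_NEWICK)
}

#' Data-source flags for the 19 study taxa
#'
#' Which species are represented by genome assemblies versus transcriptome
#' assemblies in the comparative dataset.
#'
#' @return named character vector (`"genome"`/`"transcriptome"`).
#' @export
euglenozoa_sources <- function() {
  c(Ngru = "genome", Rcos = "transcriptome", Egra = "transcriptome",
    Egym = "transcriptome", Hpha = "transcriptome", Rhum = "transcriptome",
    Sspe = "transcriptome", Perk = "genome", PhF6 = "transcriptome",
    PhM4 = "transcriptome", Ndes = "transcriptome", Ahoy = "transcriptome",
    Tbor = "transcriptome", Bsal = "genome", Pcon = "genome",
    Lmaj = "genome", Lpyr = "genome", Tbru = "genome", Tgra = "genome")
}

#' Taxonomic species groups for group-level presence calls
#'
#' The standard clade groupings with their presence thresholds: a feature
#' is present in a group when found in at least two member species, except
#' Prokinetoplastina where one species suffices. `kinetoplastids` overlaps
#' `prokinetoplastina`; pass `allow_overlap = TRUE` to
#' [group_presence()] when using both.
#'
#' @return named list of [species_group()] objects.
#' @export
euglenozoa_groups <- function() {
  list(
    diplonemids = species_group("diplonemids", c("Hpha", "Rhum", "Sspe"), 2L),
    euglenids = species_group("euglenids", c("Rcos", "Egra", "Egym"), 2L),
    kinetoplastids = species_group(
      "kinetoplastids",
      c("Perk", "PhF6", "PhM4", "Ndes", "Ahoy", "Tbor", "Bsal", "Pcon",
        "Lmaj", "Lpyr", "Tbru", "Tgra"), 2L),
    prokinetoplastina = species_group("prokinetoplastina",
                                      c("Perk", "PhF6", "PhM4"), 1L)
  )
}

#' Simulate presence/absence evolution under a single-gain/loss model
#'
#' For each feature, an origin node is drawn from `origin_weights`; the
#' feature then evolves down the subtree, being lost on each eligible
#' branch with probability `loss_prob` (everything below a loss is
#' absent). Leaf presence is "gained above and never lost on the path".
#' This is exactly the generative process Dollo parsimony assumes, so the
#' recorded truth satisfies the single-origin constraint by construction.
#'
#' @param tree a `rooted_tree`.
#' @param n_features number of features (matrix columns).
#' @param origin_weights named non-negative weights over node ids (default
#'   uniform over all nodes); use e.g. `c(<root> = 1)` for root-only
#'   origins.
#' @param loss_prob per-branch loss probability in `[0, 1]`.
#' @param loss_branches `"all"` (default) or `"terminal"` (losses only on
#'   branches leading to leaves).
#' @param source per-species source flags (see [presence_matrix()]).
#' @param seed integer seed; same seed gives bit-identical output.
#' @return list with `matrix` (a [presence_matrix()]) and `truth` (a
#'   `simulation_truth`: data frame `feature`, `origin`, `losses`
#'   semicolon-joined, plus list-column access via
#'   `attr(truth, "loss_list")`).
#' @export
simulate_dollo_matrix <- function(tree, n_features, origin_weights = NULL,
                                  loss_prob = 0.1,
                                  loss_branches = c("all", "terminal"),
                                  source = NULL, seed = 1L) {
  stopifnot(inherits(tree, "rooted_tree"), n_features >= 1L,
            loss_prob >= 0, loss_prob <= 1)
  loss_branches <- match.arg(loss_branches)
  ids <- tree$ids
  if (is.null(origin_weights)) {
    origin_weights <- stats::setNames(rep(1, length(ids)), ids)
  }
  bad <- setdiff(names(origin_weights), ids)
  if (length(bad)) {
    stop("origin weights for unknown nodes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  w <- stats::setNames(rep(0, length(ids)), ids)
  w[names(origin_weights)] <- origin_weights
  if (any(w < 0) || sum(w) == 0) {
    stop("origin weights must be >= 0 and not all zero", call. = FALSE)
  }
  set.seed(seed)
  origins <- sample(ids, n_features, replace = TRUE, prob = w)
  preorder <- rev(tree_postorder(tree))
  is_leaf <- stats::setNames(ids %in% tree$leaves, ids)
  mat <- matrix(0L, nrow = length(tree$leaves), ncol = n_features,
                dimnames = list(tree$leaves,
                                sprintf("K%05d", seq_len(n_features))))
  loss_list <- vector("list", n_features)
  for (j in seq_len(n_features)) {
    origin <- origins[j]
    alive <- stats::setNames(logical(length(ids)), ids)
    alive[origin] <- TRUE
    losses <- character(0)
    started <- FALSE
    for (nd in preorder) {
      if (nd == origin) { started <- TRUE; next }
      if (!started) next
      par <- tree$parent[[nd]]
      if (is.na(par) || !alive[par]) next
      eligible <- loss_branches == "all" || is_leaf[nd]
      if (eligible && stats::runif(1) < loss_prob) {
        losses <- c(losses, nd)
      } else {
        alive[nd] <- TRUE
      }
    }
    loss_list[[j]] <- sort(losses)
    mat[, j] <- as.integer(alive[tree$leaves])
  }
  truth <- data.frame(
    feature = colnames(mat), origin = origins,
    losses = vapply(loss_list, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  attr(truth, "loss_list") <- stats::setNames(loss_list, colnames(mat))
  class(truth) <- c("simulation_truth", class(truth))
  list(matrix = presence_matrix(mat, source = source), truth = truth)
}

#' Apply transcriptome dropout to a presence matrix
#'
#' Each presence cell of a transcriptome-flagged species independently
#' flips to absence with the given probability, emulating genes missing
#' from a transcriptome assembly because they were not expressed.
#' Requesting dropout for a genome-flagged species is an error.
#'
#' @param pm a [presence_matrix()].
#' @param dropout either a single probability applied to every
#'   transcriptome-flagged species, or a named vector over (a subset of)
#'   the transcriptome species.
#' @param seed integer seed.
#' @return list with `matrix` (the perturbed [presence_matrix()]) and
#'   `flips` (data frame `species`, `feature` of the cells flipped 1 -> 0).
#' @export
apply_missingness <- function(pm, dropout, seed = 1L) {
  stopifnot(inherits(pm, "presence_matrix"))
  if (is.null(names(dropout))) {
    stopifnot(length(dropout) == 1L)
    dropout <- stats::setNames(
      rep(dropout, sum(pm$source == "transcriptome")),
      pm$species[pm$source == "transcriptome"])
  }
  stopifnot(all(dropout >= 0), all(dropout <= 1))
  bad <- names(dropout)[pm$source[names(dropout)] != "transcriptome"]
  if (length(bad) || anyNA(pm$source[names(dropout)])) {
    stop("dropout requested for genome-flagged or unknown species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  mat <- pm$matrix
  flips <- list()
  for (sp in names(dropout)) {
    ones <- which(mat[sp, ] == 1L)
    if (!length(ones)) next
    hit <- ones[stats::runif(length(ones)) < dropout[[sp]]]
    if (length(hit)) {
      mat[sp, hit] <- 0L
      flips[[sp]] <- data.frame(species = sp, feature = pm$features[hit],
                                stringsAsFactors = FALSE)
    }
  }
  flips <- if (length(flips)) do.call(rbind, flips) else
    data.frame(species = character(0), feature = character(0))
  rownames(flips) <- NULL
  list(matrix = presence_matrix(mat, source = pm$source,
                                categories = pm$categories),
       flips = flips)
}

#' Simulate per-query homology hit tables
#'
#' Generates ranked best-hit tables with a controlled bacterial fraction
#' among the retained top hits, to exercise the decontamination rule.
#' Bitscores are strictly decreasing within a query; the number of
#' bacterial labels among the top `min(n_hits, 20)` hits matches
#' `round(fraction * n)` exactly, at shuffled ranks.
#'
#' @param n_queries number of queries.
#' @param n_hits hits per query (single value or per-query vector).
#' @param bacterial_fraction bacterial fraction per query (single value or
#'   per-query vector), in `[0, 1]`.
#' @param seed integer seed.
#' @return data frame (`query`, `subject`, `class`, `bitscore`, `evalue`,
#'   `qstart`, `qend`) with the per-query expected decision
#'   (`fraction > 0.6`) in attribute `"truth"`.
#' @export
simulate_hit_table <- function(n_queries, n_hits = 20L,
                               bacterial_fraction = 0.5, seed = 1L) {
  stopifnot(n_queries >= 1L,
            all(bacterial_fraction >= 0), all(bacterial_fraction <= 1))
  n_hits <- rep_len(as.integer(n_hits), n_queries)
  frac <- rep_len(bacterial_fraction, n_queries)
  set.seed(seed)
  out <- vector("list", n_queries)
  for (q in seq_len(n_queries)) {
    n <- n_hits[q]
    n_used <- min(n, 20L)
    n_bact <- round(frac[q] * n_used)
    cls <- rep("eukaryotic", n)
    cls[sample(n_used, n_bact)] <- "bacterial"
    bitscore <- round(500 - seq_len(n) * stats::runif(n, 1, 3), 1)
    bitscore <- rev(sort(bitscore))          # strictly decreasing w.h.p.
    bitscore <- bitscore - seq_len(n) * 1e-3 # enforce strictness
    qstart <- sample(1:50, n, replace = TRUE)
    out[[q]] <- data.frame(
      query = sprintf("q%04d", q),
      subject = sprintf("q%04d_s%03d", q, seq_len(n)),
      class = cls,
      bitscore = bitscore,
      evalue = 10^(-bitscore / 10),
      qstart = qstart,
      qend = qstart + sample(100:500, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "truth") <- data.frame(
    query = sprintf("q%04d", seq_len(n_queries)),
    bacterial_fraction = round(frac * pmin(n_hits, 20L)) / pmin(n_hits, 20L),
    expected = ifelse(round(frac * pmin(n_hits, 20L)) / pmin(n_hits, 20L)
                      > 0.6, "exclude", "keep"),
    stringsAsFactors = FALSE
  )
  res
}

#' Simulate histone H3-like aligned sequences with implanted features
#'
#' Emits aligned query/canonical pairs per class: `caH3` (near-identical
#' to the reference), `cenH3` (loop-1 insertion, scrambled N-tail,
#' glutamine substitution, divergent fold), and `H3V` (scrambled tail and
#' glutamine substitution only, no insertion, fold conserved). Mutation
#' counts are fixed per class so the implanted features deterministically
#' satisfy (or fail) the classifier criteria at its default thresholds.
#'
#' @param n_per_class sequences per class.
#' @param regions a [histone_regions()].
#' @param classes which classes to emit.
#' @param seed integer seed.
#' @return data frame with columns `id`, `label`, `query`, `canonical`
#'   (aligned rows).
#' @export
simulate_histones <- function(n_per_class, regions = histone_regions(),
                              classes = c("caH3", "cenH3", "H3V"),
                              seed = 1L) {
  stopifnot(inherits(regions, "histone_regions"), n_per_class >= 1L)
  classes <- match.arg(classes, several.ok = TRUE)
  set.seed(seed)
  ref <- strsplit(regions$reference, "")[[1]]
  mutate_region <- function(q, iv, n_mut) {
    pos <- sample(seq(iv[1], iv[2]), n_mut)
    for (p in pos) q[p] <- sample(setdiff(AA_CODES, ref[p]), 1)
    q
  }
  tail_len <- regions$tail[2] - regions$tail[1] + 1L
  fold_len <- regions$fold[2] - regions$fold[1] + 1L
  make_one <- function(label, idx) {
    q <- ref
    ins_at <- NA_integer_
    ins_seq <- character(0)
    if (label == "caH3") {
      # a few benign substitutions away from the diagnostic sites
      safe <- setdiff(seq(regions$fold[1], regions$fold[2]),
                      regions$glutamine_col)
      pos <- sample(safe, 2L)
      for (p in pos) q[p] <- sample(setdiff(AA_CODES, ref[p]), 1)
    } else {
      # divergent tail (identity ~0.35 < 0.5) and missing glutamine
      q <- mutate_region(q, regions$tail, ceiling(0.65 * tail_len))
      q[regions$glutamine_col] <- sample(setdiff(AA_CODES, "Q"), 1)
      if (label == "cenH3") {
        # divergent fold (identity ~0.6 < 0.75), sparing the Q column
        n_mut <- ceiling(0.4 * fold_len)
        repeat {
          pos <- sample(seq(regions$fold[1], regions$fold[2]), n_mut)
          if (!regions$glutamine_col %in% pos) break
        }
        for (p in pos) q[p] <- sample(setdiff(AA_CODES, ref[p]), 1)
        ins_at <- sample(seq(regions$loop1[1], regions$loop1[2] - 1L), 1)
        ins_seq <- sample(AA_CODES, sample(1:3, 1), replace = TRUE)
      }
    }
    # build aligned rows; insertion = gap columns in the canonical row
    if (is.na(ins_at)) {
      qa <- q; ca <- ref
    } else {
      qa <- append(q, ins_seq, after = ins_at)
      ca <- append(ref, rep("-", length(ins_seq)), after = ins_at)
    }
    data.frame(id = sprintf("%s_%03d", label, idx), label = label,
               query = paste(qa, collapse = ""),
               canonical = paste(ca, collapse = ""),
               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, lapply(classes, function(cl) {
    do.call(rbind, lapply(seq_len(n_per_class), function(i) make_one(cl, i)))
  }))
  rownames(res) <- NULL
  res
}

#' Simulate block-structured binary profiles
#'
#' Builds `n_blocks` groups of species with small within-block and large
#' between-block normalized Hamming distances, for benchmarking embedding
#' and clustering stability. Block centers are independent Bernoulli(0.5)
#' profiles (expected pairwise distance 0.5); members flip each center
#' coordinate with probability `within / 2`, giving expected within-block
#' pairwise distances close to `within`.
#'
#' @param n_blocks number of blocks.
#' @param per_block species per block.
#' @param n_features profile length.
#' @param within target within-block pairwise distance (default 0.05).
#' @param seed integer seed.
#' @return list with `matrix` (a [presence_matrix()]) and `blocks` (named
#'   integer vector of true block labels).
#' @export
simulate_block_matrix <- function(n_blocks = 3L, per_block = 5L,
                                  n_features = 1000L, within = 0.05,
                                  seed = 1L) {
  stopifnot(n_blocks >= 2L, per_block >= 1L, within >= 0, within < 1)
  set.seed(seed)
  centers <- matrix(stats::rbinom(n_blocks * n_features, 1L, 0.5),
                    nrow = n_blocks)
  species <- sprintf("b%d_s%d", rep(seq_len(n_blocks), each = per_block),
                     rep(seq_len(per_block), n_blocks))
  mat <- matrix(0L, nrow = length(species), ncol = n_features,
                dimnames = list(species, sprintf("K%05d", seq_len(n_features))))
  blocks <- stats::setNames(rep(seq_len(n_blocks), each = per_block), species)
  for (i in seq_along(species)) {
    flips <- stats::runif(n_features) < within / 2
    mat[i, ] <- as.integer(xor(centers[blocks[i], ] == 1L, flips))
  }
  list(matrix = presence_matrix(mat), blocks = blocks)
}
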