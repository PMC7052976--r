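#' Construct a presence/absence matrix object
#'
#' A `presence_matrix` is a species x feature binary matrix with a
#' per-species data-source flag (`"genome"` or `"transcriptome"`) and an
#' optional feature-to-category map. Features are typically KEGG Orthology
#' (KO) identifiers and categories are KEGG BRITE functional categories
#' (e.g. "Amino acid metabolism").
#'
#' @param mat a numeric/logical matrix with species as rownames and feature
#'   ids as colnames; every cell must be 0 or 1.
#' @param source named character vector over the species, values in
#'   `c("genome", "transcriptome")`; unspecified species default to
#'   `"genome"`.
#' @param categories optional data frame with columns `ko` and `path`
#'   (semicolon-separated category path, e.g.
#'   `"Metabolism;Amino acid metabolism"`); multiple rows per KO allowed.
#' @return an object of class `presence_matrix` with components `matrix`
#'   (integer 0/1), `species`, `features`, `source`, `categories`.
#' @export
presence_matrix <- function(mat, source = NULL, categories = NULL) {
  stopifnot(is.matrix(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    if (ncol(mat) == 0L && !is.null(rownames(mat))) {
      colnames(mat) <- character(0)
    } else {
      stop("matrix must have species rownames and feature colnames",
           call. = FALSE)
    }
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate species ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) {
    stop("duplicate feature ids", call. = FALSE)
  }
  storage.mode(mat) <- "integer"
  if (length(mat) && !all(mat %in% c(0L, 1L))) {
    bad <- which(!(mat %in% c(0L, 1L)))[1L]
    stop("non-binary cell in presence matrix (first offender index ", bad, ")",
         call. = FALSE)
  }
  species <- rownames(mat)
  src <- stats::setNames(rep("genome", length(species)), species)
  if (!is.null(source)) {
    if (is.null(names(source))) {
      stopifnot(length(source) == length(species))
      names(source) <- species
    }
    unknown <- setdiff(names(source), species)
    if (length(unknown)) {
      stop("source flag for unknown species: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (!all(source %in% c("genome", "transcriptome"))) {
      stop("source flags must be 'genome' or 'transcriptome'", call. = FALSE)
    }
    src[names(source)] <- source
  }
  if (!is.null(categories)) categories <- validate_categories(categories)
  structure(
    list(matrix = mat, species = species, features = colnames(mat),
         source = src, categories = categories),
    class = "presence_matrix"
  )
}

validate_categories <- function(categories) {
  stopifnot(is.data.frame(categories))
  if (!all(c("ko", "path") %in% names(categories))) {
    stop("category map needs columns 'ko' and 'path'", call. = FALSE)
  }
  categories$ko <- as.character(categories$ko)
  categories$path <- as.character(categories$path)
  categories
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix:", length(x$species), "species x",
      length(x$features), "features\n")
  cat("sources:", sum(x$source == "genome"), "genome,",
      sum(x$source == "transcriptome"), "transcriptome\n")
  invisible(x)
}

#' Read a per-species KO annotation table
#'
#' Expects a TSV with columns `species`, `protein_id`, `ko` (header
#' required). Duplicate (species, ko) assignments are allowed; they collapse
#' to a single presence when the matrix is built.
#'
#' @param path TSV file path.
#' @return a data frame with columns `species`, `protein_id`, `ko`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "protein_id", "ko")
  if (!all(need %in% names(df))) {
    stop("annotation table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df[need]
}

#' Read a KO-to-category map
#'
#' Two-column TSV (`ko`, `path`) derived from a KEGG BRITE flat export; the
#' path is semicolon-separated from the top BRITE level down, e.g.
#' `"Metabolism;Carbohydrate metabolism"`. The package never queries KEGG.
#'
#' @param path TSV file path.
#' @return data frame with columns `ko`, `path`.
#' @export
read_categories <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_categories(df)
}

#' Build a presence/absence matrix from annotation tables
#'
#' `cell(s, k) = 1` iff at least one protein of species `s` was assigned KO
#' `k`; duplicate assignments collapse. With `metabolism_only = TRUE` the
#' feature set is restricted to KOs whose category path contains the
#' top-level KEGG category "Metabolism" (the paper-style metabolic subset).
#'
#' @param annotations data frame with columns `species`, `protein_id`, `ko`
#'   (see [read_annotations()]).
#' @param categories optional KO-to-category map (see [read_categories()]);
#'   required when `metabolism_only = TRUE`. KOs missing from the map are
#'   kept but flagged with a warning and recorded in the
#'   `"unknown_kos"` attribute.
#' @param metabolism_only restrict features to the "Metabolism" category.
#' @param species optional full species list; species with no annotation
#'   records get an all-zero row (with a warning).
#' @param source per-species source flags (see [presence_matrix()]).
#' @return a [presence_matrix()].
#' @examples
#' ann <- data.frame(species = "S", protein_id = c("p1", "p2", "p3"),
#'                   ko = c("K00001", "K00001", "K00002"))
#' pm <- build_matrix(ann)
#' unique_ko_counts(pm)  # S: 2
#' @export
build_matrix <- function(annotations, categories = NULL,
                         metabolism_only = FALSE, species = NULL,
                         source = NULL) {
  stopifnot(is.data.frame(annotations))
  need <- c("species", "ko")
  if (!all(need %in% names(annotations))) {
    stop("annotations need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ann <- annotations
  ann$species <- as.character(ann$species)
  ann$ko <- as.character(ann$ko)
  bad_ko <- unique(ann$ko[!grepl("^K\\d{5}$", ann$ko)])
  if (length(bad_ko)) {
    stop("malformed KO id(s): ", paste(utils::head(bad_ko, 5), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(species)) {
    species <- unique(ann$species)
  } else {
    species <- as.character(species)
    extra <- setdiff(ann$species, species)
    if (length(extra)) {
      stop("annotations contain species not in 'species': ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  empty <- setdiff(species, unique(ann$species))
  if (length(empty)) {
    warning("species with no annotations (all-zero rows): ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  unknown <- character(0)
  if (!is.null(categories)) {
    categories <- validate_categories(categories)
    unknown <- sort(setdiff(unique(ann$ko), categories$ko))
    if (length(unknown)) {
      warning(length(unknown), " KO id(s) missing from the category map",
              call. = FALSE)
    }
  }
  features <- sort(unique(ann$ko))
  if (metabolism_only) {
    if (is.null(categories)) {
      stop("metabolism_only = TRUE requires a category map", call. = FALSE)
    }
    keep <- metabolism_kos(categories)
    features <- intersect(features, keep)
  }
  mat <- matrix(0L, nrow = length(species), ncol = length(features),
                dimnames = list(species, features))
  hit <- ann$ko %in% features
  if (any(hit)) {
    mat[cbind(ann$species[hit], ann$ko[hit])] <- 1L
  }
  pm <- presence_matrix(mat, source = source, categories = categories)
  attr(pm, "unknown_kos") <- unknown
  pm
}

# KOs whose category path includes the top-level "Metabolism" level
metabolism_kos <- function(categories) {
  paths <- strsplit(categories$path, ";", fixed = TRUE)
  hit <- vapply(paths, function(p) "Metabolism" %in% trimws(p), logical(1))
  unique(categories$ko[hit])
}

# one category per KO per top-level category: the level below "Metabolism"
# when present (e.g. "Amino acid metabolism"), else the first path element
feature_categories <- function(categories) {
  paths <- strsplit(categories$path, ";", fixed = TRUE)
  cat <- vapply(paths, function(p) {
    p <- trimws(p)
    if (length(p) >= 2L) p[[2L]] else p[[1L]]
  }, character(1))
  unique(data.frame(ko = categories$ko, category = cat,
                    stringsAsFactors = FALSE))
}

#' Write / read a presence matrix as TSV
#'
#' The TSV has one row per species: columns `species`, `source`, then one
#' 0/1 column per feature. The round-trip is lossless (the category map is
#' not serialized).
#'
#' @param pm a [presence_matrix()].
#' @param path TSV file path.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns a [presence_matrix()].
#' @export
write_matrix_tsv <- function(pm, path) {
  stopifnot(inherits(pm, "presence_matrix"))
  df <- data.frame(species = pm$species, source = unname(pm$source),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (length(pm$features)) {
    df <- cbind(df, as.data.frame(pm$matrix, check.names = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L) {
    stop("ragged TSV: rows have ", paste(unique(nf), collapse = "/"),
         " fields", call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("species", "source") %in% names(df))) {
    stop("matrix TSV needs 'species' and 'source' columns", call. = FALSE)
  }
  feat <- setdiff(names(df), c("species", "source"))
  mat <- as.matrix(df[feat])
  if (length(mat) && !all(mat %in% c(0, 1))) {
    stop("non-binary cell(s) in matrix TSV", call. = FALSE)
  }
  if (length(feat) == 0L) {
    mat <- matrix(0L, nrow = nrow(df), ncol = 0L)
  }
  rownames(mat) <- df$species
  colnames(mat) <- feat
  presence_matrix(mat, source = stats::setNames(df$source, df$species))
}
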