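# shared in-code fixtures; no data files

toy_tree4 <- function() read_newick("((A,B)N1,(C,D)N2)R;")

toy_tree6 <- function() read_newick("(((A,B)N1,C)N2,((D,E)N3,F)N4)R;")

# presence matrix from a named list of 0/1 feature vectors (species rows)
toy_matrix <- function(rows, features = NULL, source = NULL) {
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(rows)
  if (is.null(features)) features <- sprintf("K%05d", seq_len(ncol(mat)))
  colnames(mat) <- features
  presence_matrix(mat, source = source)
}

# random presence matrix + disjoint random groups, for property tests
random_group_case <- function(seed) {
  set.seed(seed)
  n_sp <- sample(5:10, 1)
  n_ft <- sample(10:30, 1)
  mat <- matrix(rbinom(n_sp * n_ft, 1, runif(1, 0.2, 0.8)), nrow = n_sp,
                dimnames = list(sprintf("sp%02d", seq_len(n_sp)),
                                sprintf("K%05d", seq_len(n_ft))))
  pm <- presence_matrix(mat)
  n_gr <- sample(2:4, 1)
  assignment <- sample(rep_len(seq_len(n_gr), n_sp))
  groups <- lapply(seq_len(n_gr), function(g) {
    members <- rownames(mat)[assignment == g]
    species_group(paste0("G", g), members,
                  min_present = sample(seq_len(length(members)), 1))
  })
  list(pm = pm, groups = groups)
}
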