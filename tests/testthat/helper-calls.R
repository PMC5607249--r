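# Builders for small in-code fixtures shared across tests.

make_calls <- function(chrom, start, end, type = "deletion",
                       sample_id = NULL, n_probes = 30) {
  n <- max(length(chrom), length(start), length(end), length(type))
  if (is.null(sample_id)) sample_id <- sprintf("S%03d", seq_len(n))
  as_cnv_calls(data.frame(sample_id = sample_id, chrom = chrom, start = start,
                          end = end, type = type, n_probes = n_probes))
}

make_manifest <- function(n_cases = 2, n_controls = 2,
                          case_sex = "male", control_sex = "male") {
  as_sample_manifest(data.frame(
    sample_id = c(sprintf("case%03d", seq_len(n_cases)),
                  sprintf("ctrl%03d", seq_len(n_controls))),
    sex = c(rep_len(case_sex, n_cases), rep_len(control_sex, n_controls)),
    group = rep(c("case", "control"), c(n_cases, n_controls))))
}

# Random overlap-prone call set: calls are jittered copies of a few anchor
# intervals, so the 80% clustering relation is exercised near its boundary.
random_calls <- function(n, n_anchors = 12, seed = 1) {
  set.seed(seed)
  anchor_chrom <- sample(c("1", "2", "X"), n_anchors, replace = TRUE)
  anchor_start <- floor(runif(n_anchors, 1e6, 5e7))
  anchor_len <- floor(runif(n_anchors, 2e4, 5e5))
  pick <- sample(n_anchors, n, replace = TRUE)
  jitter <- floor(runif(n, -0.3, 0.3) * anchor_len[pick])
  stretch <- runif(n, 0.7, 1.3)
  start <- pmax(1, anchor_start[pick] + jitter)
  make_calls(chrom = anchor_chrom[pick], start = start,
             end = start + pmax(1e4, floor(anchor_len[pick] * stretch)),
             type = sample(c("deletion", "duplication"), n, replace = TRUE),
             sample_id = sprintf("S%03d", sample(40, n, replace = TRUE)))
}

# O(n^2) clustering oracle: full pairwise reciprocal-overlap adjacency,
# connected components via igraph. Returns a canonical partition label.
oracle_cluster <- function(calls, min_overlap = 0.8) {
  n <- nrow(calls)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (calls$type[i] != calls$type[j]) next
      ro <- reciprocal_overlap(calls$chrom[i], calls$start[i], calls$end[i],
                               calls$chrom[j], calls$start[j], calls$end[j])
      adj[i, j] <- ro >= min_overlap
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# canonical form of a partition for comparison: sort members within
# components, components by first member key
partition_key <- function(calls, labels) {
  key <- paste(calls$sample_id, calls$chrom, calls$start, calls$end, calls$type)
  comps <- split(key, labels)
  comps <- lapply(comps, sort)
  unname(sort(vapply(comps, paste, character(1), collapse = "|")))
}
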