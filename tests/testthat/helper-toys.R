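# hand-built toy inputs shared across test files

# probe table with one spot per gene, bg = 0, values given per
# (gene x sample) matrix; conditions/replicas taken from dimnames-style args
toy_probe_table <- function(values, conditions, n_replicas) {
  genes <- rownames(values)
  stopifnot(ncol(values) == length(conditions) * n_replicas)
  rows <- list()
  s <- 0L
  for (cond in conditions) {
    for (k in seq_len(n_replicas)) {
      s <- s + 1L
      rows[[s]] <- data.frame(
        probe_id = paste0(genes, "_s1"), gene = genes,
        condition = cond, replica = k,
        fg = values[, s], bg = 0, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# minimal gfp_eset built directly from an aggregated matrix (one spot per
# gene, spot values equal to the aggregate) — for descriptor-level tests
# that need full control over the normalized values
toy_eset <- function(a, conditions, n_replicas) {
  skeys <- paste(rep(conditions, each = n_replicas),
                 rep(seq_len(n_replicas), length(conditions)), sep = ".")
  colnames(a) <- skeys
  spots <- lapply(rownames(a), function(g)
    matrix(a[g, ], 1, ncol(a), dimnames = list(NULL, skeys)))
  names(spots) <- rownames(a)
  structure(list(
    a = a, spots = spots,
    samples = data.frame(condition = rep(conditions, each = n_replicas),
                         replica = rep(seq_len(n_replicas),
                                       length(conditions))),
    upsilon = structure(rep(1L, nrow(a)), names = rownames(a))),
    class = "gfp_eset")
}
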