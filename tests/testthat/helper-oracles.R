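# Naive per-cell reference implementations, kept deliberately independent
# of the package's vectorised code paths: explicit loops, no table(),
# no tapply().

oracle_prevalence <- function(sc, tau) {
  clusters <- sort(unique(sc$cluster_id))
  out <- data.frame(cluster_id = clusters,
                    n_total = 0L, n_pos = 0L, fraction = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sc))) {
    j <- which(out$cluster_id == sc$cluster_id[i])
    out$n_total[j] <- out$n_total[j] + 1L
    if (sc$marker_count[i] >= tau) out$n_pos[j] <- out$n_pos[j] + 1L
  }
  out$fraction <- out$n_pos / out$n_total
  out
}

# Composition of the positive population by walking cells one at a time.
oracle_composition <- function(sc, taxonomy, tau) {
  counts <- stats::setNames(rep(0L, 4), atlasxref:::NT_CLASSES)
  n_pos <- 0L
  for (i in seq_len(nrow(sc))) {
    if (sc$marker_count[i] < tau) next
    n_pos <- n_pos + 1L
    j <- which(taxonomy$cluster_id == sc$cluster_id[i])
    cls <- if (length(j)) taxonomy$nt_class[j] else "unassigned"
    counts[cls] <- counts[cls] + 1L
  }
  list(n_pos = counts, N_pos = n_pos, pct = 100 * counts / n_pos)
}

# Expected positives per structure by summing f_{cluster(i)} over
# individual retained spatial cells (relevant clusters only).
oracle_expected <- function(st, prev, min_npos = 1L) {
  f <- stats::setNames(prev$fraction, prev$cluster_id)
  relevant <- prev$cluster_id[prev$n_pos >= min_npos]
  e <- list()
  n <- list()
  for (i in seq_len(nrow(st))) {
    k <- st$cluster_id[i]
    if (!(k %in% relevant)) next
    s <- st$structure[i]
    e[[s]] <- (if (is.null(e[[s]])) 0 else e[[s]]) + f[[k]]
    n[[s]] <- (if (is.null(n[[s]])) 0L else n[[s]]) + 1L
  }
  structures <- sort(names(e))
  data.frame(structure = structures,
             n_cells = vapply(structures, function(s) n[[s]], integer(1)),
             expected_pos = vapply(structures, function(s) e[[s]], numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Per-structure, per-class expected positives, again cell by cell.
oracle_expected_by_class <- function(st, prev, taxonomy, min_npos = 1L) {
  f <- stats::setNames(prev$fraction, prev$cluster_id)
  relevant <- prev$cluster_id[prev$n_pos >= min_npos]
  cls_of <- stats::setNames(taxonomy$nt_class, taxonomy$cluster_id)
  e <- new.env()
  for (i in seq_len(nrow(st))) {
    k <- st$cluster_id[i]
    if (!(k %in% relevant)) next
    key <- paste(st$structure[i], cls_of[[k]])
    e[[key]] <- (if (is.null(e[[key]])) 0 else e[[key]]) + f[[k]]
  }
  as.list(e)
}
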