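# Internal interval arithmetic. Every interval in the package is 0-based,
# half-open [start, end) on genomic coordinates, stored as a two-column
# integer matrix with columns "start" and "end", rows sorted by start.

iv <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  if (nrow(m) && any(m[, 1L] >= m[, 2L]))
    stop("interval start must be < end")
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

iv_empty <- function() iv(integer(0), integer(0))

# merge overlapping/adjacent intervals into a disjoint union
iv_union <- function(m) {
  if (nrow(m) <= 1L) return(m)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  s <- m[1L, 1L]; e <- m[1L, 2L]
  out_s <- integer(0); out_e <- integer(0)
  for (i in 2:nrow(m)) {
    if (m[i, 1L] > e) {
      out_s <- c(out_s, s); out_e <- c(out_e, e)
      s <- m[i, 1L]; e <- m[i, 2L]
    } else {
      e <- max(e, m[i, 2L])
    }
  }
  iv(c(out_s, s), c(out_e, e))
}

iv_width <- function(m) sum(m[, 2L] - m[, 1L])

# total overlapping bases between two interval sets (unions taken first)
iv_overlap <- function(a, b) {
  a <- iv_union(a); b <- iv_union(b)
  if (!nrow(a) || !nrow(b)) return(0L)
  tot <- 0L
  for (i in seq_len(nrow(a))) {
    o <- pmin(a[i, 2L], b[, 2L]) - pmax(a[i, 1L], b[, 1L])
    tot <- tot + sum(o[o > 0L])
  }
  as.integer(tot)
}

iv_contains_point <- function(m, pos) {
  nrow(m) > 0L && any(pos >= m[, 1L] & pos < m[, 2L])
}

# does any row of m fully contain [s, e)?
iv_contains_interval <- function(m, s, e) {
  nrow(m) > 0L && any(m[, 1L] <= s & m[, 2L] >= e)
}

# key strings for set membership of junctions
iv_keys <- function(m) {
  if (!nrow(m)) return(character(0))
  paste(m[, 1L], m[, 2L], sep = "-")
}
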