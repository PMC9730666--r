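# Internal helpers shared across modules.

# Byte-order string comparison, independent of locale collation.
.str_lt <- function(a, b) {
  ra <- utf8ToInt(a)
  rb <- utf8ToInt(b)
  n <- min(length(ra), length(rb))
  if (n > 0L) {
    d <- ra[seq_len(n)] - rb[seq_len(n)]
    nz <- which(d != 0L)
    if (length(nz) > 0L) return(d[nz[1L]] < 0L)
  }
  length(ra) < length(rb)
}

# Lexicographic comparison of two token vectors (byte order per token).
.tokens_lt <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0L) {
    d <- which(a[seq_len(n)] != b[seq_len(n)])
    if (length(d) > 0L) return(.str_lt(a[d[1L]], b[d[1L]]))
  }
  length(a) < length(b)
}

# Deterministic byte-order sort permutation for character vectors.
.radix_order <- function(...) order(..., method = "radix")

.flip_orient <- function(o) ifelse(o == "+", "-", "+")

.other_side <- function(side) ifelse(side == "head", "tail", "head")

.end_key <- function(contig, side) paste(contig, side, sep = ":")

.key_contig <- function(key) sub(":(head|tail)$", "", key)

.key_side <- function(key) sub("^.*:", "", key)

# Vectorized lookup of symmetric triplet values; absent pairs return 0.
.lookup_values <- function(mat, qi, qj) {
  i <- pmin(qi, qj)
  j <- pmax(qi, qj)
  dt <- data.table::data.table(i = mat$i, j = mat$j, value = mat$value,
                               key = c("i", "j"))
  q <- data.table::data.table(i = i, j = j)
  v <- dt[q, on = c("i", "j")]$value
  v[is.na(v)] <- 0
  v
}
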