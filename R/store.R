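# Chunked ring storage for the replay and auxiliary buffers. Writing a
# row touches only one small chunk, so appends stay cheap even when the
# buffer holds ~10^5 rows (subassignment into one large matrix bound in
# an environment would copy the whole matrix on every write).

store_init <- function(capacity, ncol, chunk = 256L) {
  e <- new.env(parent = emptyenv())
  e$capacity <- as.integer(capacity)
  e$ncol <- as.integer(ncol)
  e$chunk <- as.integer(chunk)
  e$chunks <- vector("list", ceiling(capacity / chunk))
  e$n <- 0L
  e$pos <- 0L
  e
}

store_add <- function(st, row) {
  st$pos <- (st$pos %% st$capacity) + 1L
  ci <- (st$pos - 1L) %/% st$chunk + 1L
  ri <- (st$pos - 1L) %% st$chunk + 1L
  ch <- st$chunks[[ci]]
  if (is.null(ch)) ch <- matrix(0, st$chunk, st$ncol)
  ch[ri, ] <- row
  st$chunks[[ci]] <- ch
  st$n <- min(st$n + 1L, st$capacity)
  invisible(st)
}

store_rows <- function(st, idx) {
  out <- matrix(0, length(idx), st$ncol)
  ci <- (idx - 1L) %/% st$chunk + 1L
  ri <- (idx - 1L) %% st$chunk + 1L
  for (i in seq_along(idx)) out[i, ] <- st$chunks[[ci[i]]][ri[i], ]
  out
}
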