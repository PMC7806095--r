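# a valid locked column of h agents at 0-based pixel (x, y)
.stackAgentsTest <- function(x, y, h) {
  st <- rep("covered", h)
  st[h] <- "locked"
  data.frame(state = st, x = as.integer(x), y = as.integer(y),
             z = seq_len(h) - 1L)
}

# build a WorldState holding only locked columns from a height map
worldFromHeights <- function(hm) {
  nz <- which(hm > 0, arr.ind = TRUE)
  ag <- do.call(rbind, lapply(seq_len(nrow(nz)), function(k)
    .stackAgentsTest(nz[k, 1] - 1L, nz[k, 2] - 1L, hm[nz[k, 1], nz[k, 2]])))
  if (is.null(ag))
    ag <- data.frame(state = character(), x = integer(), y = integer(),
                     z = integer())
  worldState(hm, ag)
}
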