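## independent oracle: score every window on both strands by explicit loops
bruteScan <- function(seq, motif, minRel = 0.8) {
  pwm <- logOdds(motif)
  L <- ncol(pwm)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  minS <- sum(apply(pwm, 2, min)); maxS <- sum(apply(pwm, 2, max))
  chars <- strsplit(toupper(seq), "")[[1]]
  hits <- list()
  for (off in 0:(nchar(seq) - L)) {
    win <- chars[off + seq_len(L)]
    if (any(!win %in% names(comp))) next
    sPlus <- sum(vapply(seq_len(L), function(k) pwm[win[k], k], 0))
    rcwin <- rev(unname(comp[win]))
    sMinus <- sum(vapply(seq_len(L), function(k) pwm[rcwin[k], k], 0))
    for (st in c("+", "-")) {
      sc <- if (st == "+") sPlus else sMinus
      rel <- (sc - minS) / (maxS - minS)
      if (rel >= minRel)
        hits[[length(hits) + 1L]] <- data.frame(position = off, strand = st,
                                                score = sc, relScore = rel)
    }
  }
  if (!length(hits)) return(NULL)
  out <- do.call(rbind, hits)
  out[order(out$position, out$strand), ]
}
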