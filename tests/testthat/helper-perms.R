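# all permutations of a short vector (test oracle; independent of the
# package's multiset enumeration)
combinat_perms <- function(x) {
  if (length(x) <= 1) {
    return(list(x))
  }
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  unique(out)
}
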