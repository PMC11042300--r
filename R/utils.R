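# internal helpers shared across modules

stop_resectr <- function(msg, class = "resectr_error") {
  rlang::abort(msg, class = c(class, "resectr_error"))
}

# validate a genome layout tibble (chrom, length)
check_layout <- function(layout, arg = "layout") {
  if (!is.data.frame(layout) || !all(c("chrom", "length") %in% names(layout))) {
    stop_resectr(sprintf("`%s` must be a data frame with columns `chrom` and `length`", arg))
  }
  if (anyDuplicated(layout$chrom)) {
    stop_resectr("chromosome names in the layout must be unique")
  }
  if (any(!is.finite(layout$length)) || any(layout$length <= 0)) {
    stop_resectr("chromosome lengths must be positive and finite")
  }
  invisible(layout)
}

layout_lengths <- function(layout) {
  setNames(as.numeric(layout$length), as.character(layout$chrom))
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_resectr("`seed` must be a single finite number")
  }
  as.integer(seed)
}

# increment counts at 0-based positions within a vector of length len
add_counts_at <- function(v, pos0) {
  if (length(pos0) == 0L) return(v)
  tab <- tabulate(pos0 + 1L, nbins = length(v))
  v + tab
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_resectr(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  x
}
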