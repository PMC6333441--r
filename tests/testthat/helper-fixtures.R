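# shared fixtures, built once per test run

.fixtures <- new.env()

# the default synthetic cell (seed 1) with its grid and a passive system
default_cell <- function() {
  if (is.null(.fixtures$cell)) {
    m <- generate_synthetic_morphology(seed = 1)
    g <- discretize(m)
    .fixtures$cell <- list(m = m, g = g, sys = compartmental_system(g))
  }
  .fixtures$cell
}

# soma (L = d = 16.24 um) plus an arbitrary dendritic tree given as vectors
toy_morphology <- function(parent, length, diam, order = NULL, root = NULL) {
  n <- base::length(parent)
  order <- order %||% rep(1L, n)
  root <- root %||% rep(1L, n)
  soma_ld <- sqrt(829 / pi)
  sec <- tibble::tibble(
    section = c(1L, seq_len(n) + 1L),
    parent = c(NA_integer_, as.integer(parent)),
    length = c(soma_ld, length),
    diam_prox = c(soma_ld, diam),
    diam_dist = c(soma_ld, diam),
    branch_order = c(0L, as.integer(order)),
    root_id = c(0L, as.integer(root)),
    is_soma = c(TRUE, rep(FALSE, n))
  )
  as_morphology(sec, soma_area = 829)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
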