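#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`, coordinates and
#' radii in um). The root record (parent -1) is taken as the soma and mapped
#' to a cylinder with length = diameter = 2 x radius, which has the same
#' membrane area as the sphere the record describes. Chains of single-child
#' records are merged into sections; branch points start new sections.
#'
#' @param path file path.
#' @return a `pir_morphology`.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  recs <- list()
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 7) {
      abort(sprintf("SWC parse error at line %d: expected 7 fields, got %d",
                    i, length(f)), class = "pir_parse_error")
    }
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v))) {
      abort(sprintf("SWC parse error at line %d: non-numeric field", i),
            class = "pir_parse_error")
    }
    recs[[length(recs) + 1L]] <- v
  }
  m <- do.call(rbind, recs)
  colnames(m) <- c("id", "type", "x", "y", "z", "radius", "parent")
  ids <- m[, "id"]
  if (anyDuplicated(ids)) abort("SWC structure error: duplicate ids",
                                class = "pir_structure_error")
  roots <- m[, "parent"] == -1
  if (sum(roots) != 1) abort("SWC structure error: need exactly one root record",
                             class = "pir_structure_error")
  nonroot_parents <- m[!roots, "parent"]
  if (!all(nonroot_parents %in% ids)) {
    abort("SWC structure error: parent id references a missing record",
          class = "pir_structure_error")
  }
  # cycle check on the record graph
  idx <- match(m[, "parent"], ids)
  for (i in seq_len(nrow(m))) {
    seen <- logical(nrow(m)); cur <- i
    while (!is.na(cur)) {
      if (seen[cur]) abort("SWC structure error: cyclic parent links",
                           class = "pir_structure_error")
      seen[cur] <- TRUE
      cur <- idx[cur]
    }
  }

  root_id <- ids[roots]
  children <- split(ids[!roots], m[!roots, "parent"])
  n_children <- function(id) length(children[[as.character(id)]] %||% integer(0))
  pos <- function(id) m[match(id, ids), c("x", "y", "z")]

  soma_radius <- unname(m[roots, "radius"])
  soma_ld <- 2 * soma_radius
  soma_area <- pi * soma_ld^2 # == 4 pi r^2

  sections <- list(tibble(
    section = 1L, parent = NA_integer_, length = soma_ld,
    diam_prox = soma_ld, diam_dist = soma_ld, branch_order = 0L,
    root_id = 0L, is_soma = TRUE
  ))
  # walk: (start record, parent section, branch order, root id)
  sec_id <- 1L
  queue <- lapply(children[[as.character(root_id)]] %||% integer(0), function(ch) {
    list(rec = ch, parent_sec = 1L, order = 1L, root = NA_integer_)
  })
  prim <- 0L
  qi <- 1L
  queue <- lapply(queue, function(q) { q }) # plain list
  while (qi <= length(queue)) {
    q <- queue[[qi]]; qi <- qi + 1L
    root <- q$root
    if (is.na(root)) { prim <- prim + 1L; root <- prim }
    # accumulate a chain of single-child records
    chain <- q$rec
    while (n_children(chain[length(chain)]) == 1) {
      chain <- c(chain, children[[as.character(chain[length(chain)])]])
    }
    prev <- m[match(q$rec, ids), "parent"]
    pts <- rbind(pos(prev), t(vapply(chain, pos, numeric(3))))
    seglen <- sqrt(rowSums(diff(pts)^2))
    len <- sum(seglen)
    if (len <= 0) abort("SWC structure error: zero-length section",
                        class = "pir_structure_error")
    r_first <- unname(m[match(chain[1], ids), "radius"])
    r_last <- unname(m[match(chain[length(chain)], ids), "radius"])
    sec_id <- sec_id + 1L
    sections[[length(sections) + 1L]] <- tibble(
      section = sec_id, parent = q$parent_sec, length = len,
      diam_prox = 2 * r_first, diam_dist = 2 * r_last,
      branch_order = q$order, root_id = root, is_soma = FALSE
    )
    for (ch in children[[as.character(chain[length(chain)])]] %||% integer(0)) {
      queue[[length(queue) + 1L]] <- list(rec = ch, parent_sec = sec_id,
                                          order = q$order + 1L, root = root)
    }
  }
  morph <- new_morphology(bind_rows(sections), soma_area)
  validate_morphology(morph)
  morph
}

#' Write a morphology to an SWC file
#'
#' Emits a standard 7-column SWC file (type 1 = soma, 4 = apical dendrite).
#' Coordinates are synthesised by laying each section out as a straight
#' segment (primaries fanned around vertical, children fanned +/- 25 deg in
#' alternating planes); path lengths and radii are preserved exactly, so
#' `read_swc(write_swc(m))` reproduces section count, lengths and distal
#' diameters.
#'
#' @param morph a `pir_morphology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(morph, path) {
  sec <- morph$sections
  soma <- sec[sec$is_soma, ]
  out <- sprintf("%d 1 %.6f %.6f %.6f %.6f %d", 1L, 0, 0, 0, soma$length / 2, -1L)

  # per-section geometric state: distal endpoint, direction, record id
  state <- list()
  state[[as.character(soma$section)]] <-
    list(end = c(0, 0, 0), dir = c(0, 0, 1), rec = 1L)
  next_rec <- 2L
  dend <- sec[!sec$is_soma, ]
  child_rank <- integer(nrow(sec)) # how many children of each parent seen
  names(child_rank) <- as.character(sec$section)
  n_prim <- sum(dend$branch_order == 1L)
  ip <- 0L
  for (i in seq_len(nrow(dend))) {
    s <- dend[i, ]
    ps <- state[[as.character(s$parent)]]
    rank <- child_rank[[as.character(s$parent)]]
    child_rank[[as.character(s$parent)]] <- rank + 1L
    if (s$branch_order == 1L) {
      ip <- ip + 1L
      ang <- 2 * pi * (ip - 1) / n_prim
      dir <- c(0.45 * cos(ang), 0.45 * sin(ang), 1)
    } else {
      spread <- if (rank %% 2 == 0) 25 else -25
      th <- spread * pi / 180
      ref <- if (abs(ps$dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      axis <- ref - sum(ref * ps$dir) / sum(ps$dir^2) * ps$dir
      axis <- axis / sqrt(sum(axis^2))
      dir <- cos(th) * ps$dir + sin(th) * axis
    }
    dir <- dir / sqrt(sum(dir^2))
    p0 <- ps$end
    # two records: a near-proximal point carrying the proximal radius, and
    # the distal endpoint
    pa <- p0 + dir * (0.001 * s$length)
    pb <- p0 + dir * s$length
    r1 <- next_rec; r2 <- next_rec + 1L; next_rec <- next_rec + 2L
    out <- c(out,
             sprintf("%d 4 %.6f %.6f %.6f %.6f %d", r1, pa[1], pa[2], pa[3],
                     s$diam_prox / 2, ps$rec),
             sprintf("%d 4 %.6f %.6f %.6f %.6f %d", r2, pb[1], pb[2], pb[3],
                     s$diam_dist / 2, r1))
    state[[as.character(s$section)]] <- list(end = pb, dir = dir, rec = r2)
  }
  writeLines(c("# generated by piriform: 7-column SWC, um", out), path)
  invisible(path)
}
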