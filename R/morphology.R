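#' Generator parameters for a synthetic apical dendritic tree
#'
#' The reconstruction summary the generator is constrained by: a ~829 um^2
#' soma, 2238--2516 um of apical dendrite, and distal tips beyond 350 um so
#' that the distal (LOT-recipient) stimulation sites used by the protocols
#' exist. Branch-order statistics and diameters are not constrained by those
#' summaries; the defaults below (three primary apical dendrites, binary
#' branching to depth four giving 24 short terminal branches, diameters
#' tapering 2.8 -> 1.8 um with branch order) put the terminal branches in
#' the regime the original model demonstrably operated in: a local NMDA
#' spike ignites at roughly 7-9 calibrated inputs, so a six-input
#' glomerulus is subthreshold on its own while two same-branch glomeruli
#' ignite reliably. Every parameter is tunable.
#'
#' @param n_primary number of primary apical dendrites leaving the soma.
#' @param length_means mean section length (um) per branch order; its length
#'   sets the branching depth.
#' @param length_cv coefficient of variation of section lengths.
#' @param diam_by_order section diameter (um) per branch order.
#' @param soma_area soma membrane area (um^2); modelled as a cylinder with
#'   length = diameter (for 829 um^2, L = d = 16.24 um).
#' @param total_length_range target range (um) for total dendritic length;
#'   the sampled tree is rescaled so its total falls in this range.
#' @param min_tip_distance guaranteed maximum path distance (um); length is
#'   redistributed onto the deepest path if the sampled tree falls short.
#' @return a list of generator parameters.
#' @export
morph_params <- function(n_primary = 3,
                         length_means = c(200, 160, 55, 25),
                         length_cv = 0.15,
                         diam_by_order = c(2.8, 2.2, 2.0, 1.8),
                         soma_area = 829,
                         total_length_range = c(2238, 2516),
                         min_tip_distance = 360) {
  list(n_primary = n_primary, length_means = length_means,
       length_cv = length_cv, diam_by_order = diam_by_order,
       soma_area = soma_area, total_length_range = total_length_range,
       min_tip_distance = min_tip_distance)
}

new_morphology <- function(sections, soma_area) {
  structure(list(sections = sections, soma_area = soma_area),
            class = "pir_morphology")
}

#' Generate a synthetic apical dendritic tree
#'
#' Builds a rooted tree of cylindrical sections: a soma cylinder plus
#' `n_primary` binary subtrees. Section lengths are drawn from normal
#' distributions per branch order, then rescaled so the total dendritic
#' length lands uniformly inside `total_length_range`; if the deepest
#' root-to-tip path then falls short of `min_tip_distance`, length is
#' transferred onto that path (total preserved) so distal stimulation sites
#' are always realisable.
#'
#' @param params see [morph_params()].
#' @param seed integer seed; the same seed reproduces the same tree.
#' @return a `pir_morphology`: a list with a `sections` tibble (section id,
#'   parent, length and diameters in um, branch order, root dendrite id) and
#'   the soma area.
#' @export
generate_synthetic_morphology <- function(params = morph_params(), seed = 1) {
  p <- params
  depth <- length(p$length_means)
  if (length(p$diam_by_order) != depth) {
    abort("constraint violated: diam_by_order must have one diameter per branch order",
          class = "pir_constraint_error")
  }
  if (p$total_length_range[1] > p$total_length_range[2] ||
      p$total_length_range[1] <= 0) {
    abort("constraint violated: total_length_range must be a positive, ordered range",
          class = "pir_constraint_error")
  }
  if (p$min_tip_distance >= p$total_length_range[1]) {
    abort("constraint violated: min_tip_distance exceeds the attainable total length",
          class = "pir_constraint_error")
  }
  if (p$n_primary < 2) {
    abort("constraint violated: n_primary must be >= 2 so sister/different branch relations exist",
          class = "pir_constraint_error")
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # soma cylinder with length = diameter: lateral area pi * L * d
  soma_ld <- sqrt(p$soma_area / pi)
  rows <- list(tibble(
    section = 1L, parent = NA_integer_, length = soma_ld,
    diam_prox = soma_ld, diam_dist = soma_ld,
    branch_order = 0L, root_id = 0L, is_soma = TRUE
  ))
  nid <- 1L
  for (prim in seq_len(p$n_primary)) {
    frontier <- list(list(parent = 1L, order = 1L))
    while (length(frontier) > 0) {
      nxt <- list()
      for (node in frontier) {
        k <- node$order
        nid <- nid + 1L
        len <- max(15, rnorm(1, p$length_means[k], p$length_cv * p$length_means[k]))
        # sections taper towards the calibre of the next branch order
        d_dist <- if (k < depth) p$diam_by_order[k + 1] else p$diam_by_order[k]
        rows[[length(rows) + 1L]] <- tibble(
          section = nid, parent = node$parent, length = len,
          diam_prox = p$diam_by_order[k], diam_dist = d_dist,
          branch_order = k, root_id = prim, is_soma = FALSE
        )
        if (k < depth) {
          nxt[[length(nxt) + 1L]] <- list(parent = nid, order = k + 1L)
          nxt[[length(nxt) + 1L]] <- list(parent = nid, order = k + 1L)
        }
      }
      frontier <- nxt
    }
  }
  sec <- bind_rows(rows)

  # rescale dendritic length into the target range
  dend <- !sec$is_soma
  target <- runif(1, p$total_length_range[1], p$total_length_range[2])
  sec$length[dend] <- sec$length[dend] * target / sum(sec$length[dend])

  morph <- new_morphology(sec, p$soma_area)

  # guarantee distal reach: stretch the deepest path, shrink the rest,
  # preserving the total
  tipd <- section_tip_distances(morph)
  if (max(tipd$tip_dist) < p$min_tip_distance) {
    deepest <- tipd$section[which.max(tipd$tip_dist)]
    path <- section_path_to_root(morph, deepest)
    onpath <- sec$section %in% path & !sec$is_soma
    P <- sum(sec$length[onpath])
    O <- sum(sec$length[dend & !onpath])
    sec$length[onpath] <- sec$length[onpath] * p$min_tip_distance / P
    sec$length[dend & !onpath] <- sec$length[dend & !onpath] *
      (target - p$min_tip_distance) / O
    morph$sections <- sec
  }
  validate_morphology(morph, total_length_range = p$total_length_range)
  morph
}

# save/restore the global RNG state so seeded generators do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Build a morphology from a section table
#'
#' Constructs a `pir_morphology` from a tibble/data.frame of sections
#' (columns `section`, `parent`, `length`, `diam_prox`, `diam_dist`,
#' `branch_order`, `root_id`, `is_soma`; exactly one soma row with `parent`
#' `NA`). The soma area defaults to the lateral area of the soma cylinder.
#'
#' @param sections section table, soma first, parents before children.
#' @param soma_area soma membrane area (um^2).
#' @export
as_morphology <- function(sections, soma_area = NULL) {
  sections <- as_tibble(sections)
  soma <- sections[sections$is_soma, ]
  if (is.null(soma_area)) soma_area <- pi * soma$length * soma$diam_prox
  morph <- new_morphology(sections, soma_area)
  validate_morphology(morph)
  morph
}

#' Validate morphology invariants
#'
#' Checks the tree is acyclic with a single soma root, all lengths and
#' diameters positive, and (optionally) total dendritic length in range.
#'
#' @param morph a `pir_morphology`.
#' @param total_length_range optional range (um) the dendritic length must be
#'   in.
#' @return `morph`, invisibly; errors on violation.
#' @export
validate_morphology <- function(morph, total_length_range = NULL) {
  sec <- morph$sections
  if (sum(sec$is_soma) != 1L || !is.na(sec$parent[sec$is_soma])) {
    abort("morphology must have exactly one soma root", class = "pir_structure_error")
  }
  if (any(sec$length <= 0) || any(sec$diam_prox <= 0) || any(sec$diam_dist <= 0)) {
    abort("all section lengths and diameters must be positive",
          class = "pir_structure_error")
  }
  non_root <- sec[!sec$is_soma, ]
  if (!all(non_root$parent %in% sec$section)) {
    abort("section parent refers to a missing section", class = "pir_structure_error")
  }
  # acyclic: walking parents must always terminate at the soma
  for (s in non_root$section) {
    seen <- integer(0)
    cur <- s
    repeat {
      if (cur %in% seen) abort("cycle detected in section tree",
                               class = "pir_structure_error")
      seen <- c(seen, cur)
      par <- sec$parent[match(cur, sec$section)]
      if (is.na(par)) break
      cur <- par
    }
  }
  if (!is.null(total_length_range)) {
    tl <- total_dendritic_length(morph)
    if (tl < total_length_range[1] - 1e-6 || tl > total_length_range[2] + 1e-6) {
      abort(sprintf("total dendritic length %.1f um outside [%g, %g]",
                    tl, total_length_range[1], total_length_range[2]),
            class = "pir_constraint_error")
    }
  }
  invisible(morph)
}

#' Total dendritic length (um), soma excluded
#' @param morph a `pir_morphology`.
#' @export
total_dendritic_length <- function(morph) {
  sum(morph$sections$length[!morph$sections$is_soma])
}

section_path_to_root <- function(morph, section) {
  sec <- morph$sections
  path <- integer(0)
  cur <- section
  while (!is.na(cur)) {
    path <- c(path, cur)
    cur <- sec$parent[match(cur, sec$section)]
  }
  path
}

# path distance (um) from the soma to the distal end of every section;
# the soma itself contributes zero
section_origin_distances <- function(morph) {
  sec <- morph$sections
  origin <- setNames(numeric(nrow(sec)), sec$section)
  # sections are created parent-first, so a single pass suffices
  for (i in seq_len(nrow(sec))) {
    s <- sec$section[i]
    par <- sec$parent[i]
    if (is.na(par)) {
      origin[as.character(s)] <- 0
    } else {
      pl <- if (sec$is_soma[match(par, sec$section)]) 0 else
        sec$length[match(par, sec$section)]
      origin[as.character(s)] <- origin[as.character(par)] + pl
    }
  }
  origin
}

section_tip_distances <- function(morph) {
  sec <- morph$sections[!morph$sections$is_soma, ]
  origin <- section_origin_distances(morph)
  tibble(section = sec$section,
         tip_dist = origin[as.character(sec$section)] + sec$length)
}

#' Terminal (tip) sections of a morphology
#' @param morph a `pir_morphology`.
#' @return integer section ids with no children.
#' @export
terminal_sections <- function(morph) {
  sec <- morph$sections
  setdiff(sec$section[!sec$is_soma], sec$parent[!is.na(sec$parent)])
}

#' A location on the dendritic tree
#'
#' @param section section id.
#' @param arc position along the section in `[0, 1]` (0 = proximal end).
#' @export
dendritic_location <- function(section, arc = 0.5) {
  stopifnot(arc >= 0, arc <= 1)
  structure(list(section = as.integer(section), arc = arc),
            class = "pir_location")
}

#' Discretize a morphology into iso-potential compartments
#'
#' Each section is split into `ceiling(length / max_seg_len)` equal
#' compartments; the soma is one compartment. Compartments are emitted in
#' Hines order (parents before children) with the axial coupling conductance
#' to their parent, so the electrical system can be solved by a single
#' elimination pass on the tree.
#'
#' The default segment length, 4.6 um, reproduces the mean compartment size
#' implied by the reconstruction counts (roughly 500 compartments for
#' ~2.4 mm of dendrite); 19 um is the admissible upper bound.
#'
#' @param morph a `pir_morphology`.
#' @param max_seg_len maximum compartment length (um), must be in (0, 19].
#' @param passive passive membrane parameters (for axial resistivity), see
#'   [passive_params()].
#' @return a `pir_grid`: a list with a `comps` tibble (compartment id,
#'   section, arc span, length, membrane area um^2, path distance to soma um,
#'   parent compartment, axial conductance uS) plus lookup metadata.
#' @export
discretize <- function(morph, max_seg_len = 4.6, passive = passive_params()) {
  stopifnot(max_seg_len > 0)
  if (max_seg_len > 19) {
    abort("max_seg_len must not exceed 19 um", class = "pir_constraint_error")
  }
  sec <- morph$sections
  origin <- section_origin_distances(morph)
  ra <- passive$Ra # ohm cm

  comp_rows <- vector("list", nrow(sec))
  # soma first
  soma <- sec[sec$is_soma, ]
  comp_rows[[1]] <- tibble(
    comp = 1L, section = soma$section, arc0 = 0, arc1 = 1,
    length = soma$length, diam = soma$diam_prox, area = morph$soma_area,
    path_dist = 0, parent_comp = NA_integer_, g_axial = NA_real_
  )
  # map from section id to the comp index at its distal end
  distal_comp <- c()
  distal_comp[as.character(soma$section)] <- 1L
  next_comp <- 2L

  dend <- sec[!sec$is_soma, ]
  for (i in seq_len(nrow(dend))) {
    s <- dend[i, ]
    nseg <- ceiling(s$length / max_seg_len)
    arcs <- seq(0, 1, length.out = nseg + 1)
    lmid <- (head(arcs, -1) + tail(arcs, -1)) / 2
    dmid <- s$diam_prox + (s$diam_dist - s$diam_prox) * lmid
    lens <- rep(s$length / nseg, nseg)
    ids <- next_comp:(next_comp + nseg - 1L)
    parents <- c(distal_comp[[as.character(s$parent)]], head(ids, -1))
    comp_rows[[i + 1L]] <- tibble(
      comp = ids, section = s$section, arc0 = head(arcs, -1), arc1 = tail(arcs, -1),
      length = lens, diam = dmid, area = pi * dmid * lens,
      path_dist = origin[[as.character(s$section)]] + lmid * s$length,
      parent_comp = parents, g_axial = NA_real_
    )
    distal_comp[as.character(s$section)] <- ids[nseg]
    next_comp <- next_comp + nseg
  }
  comps <- bind_rows(comp_rows)

  # axial conductance between compartment centres:
  # R = Ra * (l/2) / (pi r^2) on each side, Ra in ohm um after conversion
  ra_um <- ra * 1e4
  half_r <- ra_um * (comps$length / 2) / (pi * (comps$diam / 2)^2) # ohm
  g <- rep(NA_real_, nrow(comps))
  for (i in seq_len(nrow(comps))[-1]) {
    p <- comps$parent_comp[i]
    g[i] <- 1e6 / (half_r[i] + half_r[p]) # uS
  }
  comps$g_axial <- g

  structure(list(comps = comps, morph = morph, max_seg_len = max_seg_len,
                 section_origin = origin),
            class = "pir_grid")
}

#' Path distance from the soma to a dendritic location
#'
#' The sum of arc lengths along the unique path from the location to the soma
#' root (um); the soma itself is at distance 0.
#'
#' @param grid a `pir_grid`.
#' @param loc a [dendritic_location()].
#' @export
path_distance <- function(grid, loc) {
  sec <- grid$morph$sections
  i <- match(loc$section, sec$section)
  if (is.na(i)) abort("unknown section id", class = "pir_lookup_error")
  if (sec$is_soma[i]) return(0)
  grid$section_origin[[as.character(loc$section)]] + loc$arc * sec$length[i]
}

#' Classify a dendritic location into the LOT / IC / perisomatic zones
#'
#' Perisomatic: path distance <= `perisomatic_max` (100 um, the proximal
#' apical region targeted by feedback inhibition). LOT: path distance >=
#' `lot_band_start` (default 250 um, matching the distal band where olfactory
#' tract axons terminate). IC (intracortical) otherwise.
#'
#' @inheritParams path_distance
#' @param lot_band_start start of the LOT-recipient band (um).
#' @param perisomatic_max outer edge of the perisomatic zone (um).
#' @return one of `"perisomatic"`, `"IC"`, `"LOT"`.
#' @export
classify_zone <- function(grid, loc, lot_band_start = 250, perisomatic_max = 100) {
  d <- path_distance(grid, loc)
  if (d <= perisomatic_max) "perisomatic"
  else if (d >= lot_band_start) "LOT"
  else "IC"
}

#' Branch relation between two dendritic locations
#'
#' `"same"` if the two locations lie on one unbranched line of descent (one
#' location's section is an ancestor of the other's, or they share a
#' section); `"sister"` if they lie on distinct subtrees of the same primary
#' (root) dendrite; `"different"` if their primary dendrites differ.
#'
#' @param morph a `pir_morphology`.
#' @param loc_a,loc_b [dendritic_location()]s.
#' @export
branch_relation <- function(morph, loc_a, loc_b) {
  sec <- morph$sections
  for (s in c(loc_a$section, loc_b$section)) {
    if (!s %in% sec$section) abort("unknown section id", class = "pir_lookup_error")
  }
  pa <- section_path_to_root(morph, loc_a$section)
  pb <- section_path_to_root(morph, loc_b$section)
  if (loc_a$section %in% pb || loc_b$section %in% pa) return("same")
  ra <- sec$root_id[match(loc_a$section, sec$section)]
  rb <- sec$root_id[match(loc_b$section, sec$section)]
  if (ra == rb) "sister" else "different"
}

#' Morphology summary
#'
#' Totals a morphology and (optionally) its discretization: total dendritic
#' length, soma area, section and compartment counts, and per-zone dendritic
#' length. Serializable to JSON.
#'
#' @param morph a `pir_morphology`.
#' @param grid optional `pir_grid`; zone lengths and compartment counts are
#'   reported when supplied.
#' @param lot_band_start,perisomatic_max zone boundaries (um).
#' @return a named list.
#' @export
morphology_summary <- function(morph, grid = NULL, lot_band_start = 250,
                               perisomatic_max = 100) {
  out <- list(
    soma_area_um2 = morph$soma_area,
    total_dendritic_length_um = total_dendritic_length(morph),
    n_sections = sum(!morph$sections$is_soma),
    n_primary = length(unique(morph$sections$root_id[!morph$sections$is_soma]))
  )
  if (!is.null(grid)) {
    cc <- grid$comps[!is.na(grid$comps$parent_comp), ]
    zone <- ifelse(cc$path_dist <= perisomatic_max, "perisomatic",
                   ifelse(cc$path_dist >= lot_band_start, "LOT", "IC"))
    out$n_compartments <- nrow(grid$comps)
    out$zone_length_um <- as.list(tapply(cc$length, zone, sum))
    out$max_path_distance_um <- max(cc$path_dist + cc$length / 2)
  }
  out
}

#' @export
print.pir_morphology <- function(x, ...) {
  cat("<pir_morphology> ", sum(!x$sections$is_soma), " sections, ",
      sprintf("%.0f", total_dendritic_length(x)), " um dendrite, soma ",
      sprintf("%.0f", x$soma_area), " um^2\n", sep = "")
  invisible(x)
}

#' @export
print.pir_grid <- function(x, ...) {
  cat("<pir_grid> ", nrow(x$comps), " compartments (max segment ",
      x$max_seg_len, " um)\n", sep = "")
  invisible(x)
}
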