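# Morphology: deterministic axon, soma, seeded surrogate dendritic tree,
# area audit, SWC exchange.

AXON_SPEC <- list(
  AIS = c(diam = 0.97, len = 17), paraAIS = c(diam = 0.97, len = 4),
  myelin = c(diam = 0.73, len = 100), node = c(diam = 0.73, len = 4),
  collateral = c(diam = 0.6, len = 100)
)
SOMA_DIAM <- 29.8
SOMA_LEN <- 29.8

new_section <- function(id, parent, tag, diam, len) {
  data.frame(id = id, parent = parent, tag = tag, diam = diam, length = len)
}

#' Build the axonal sections
#'
#' Eleven sections: AIS (17 x 0.97 um), paraAIS (4 x 0.97), four myelinated
#' internodes of 100 x 0.73 um alternating with three nodes of Ranvier
#' (4 x 0.73), and a non-myelinated collateral of two 100 x 0.6 um sections
#' branching from the second node.  Section ids start at `id_start`; the
#' AIS parent is `parent` (normally the soma).  Deterministic.
#'
#' @param parent Section id the AIS attaches to.
#' @param id_start First id to assign.
#' @return Data frame of sections (id, parent, tag, diam, length).
#' @export
pc_build_axon <- function(parent = 1L, id_start = 2L) {
  s <- AXON_SPEC
  id <- id_start - 1L
  nxt <- function() { id <<- id + 1L; id }
  ais <- new_section(nxt(), parent, "AIS", s$AIS["diam"], s$AIS["len"])
  para <- new_section(nxt(), ais$id, "paraAIS", s$paraAIS["diam"], s$paraAIS["len"])
  prev <- para$id
  chain <- list(ais, para)
  node_ids <- integer(3)
  for (k in 1:3) {
    my <- new_section(nxt(), prev, "myelin", s$myelin["diam"], s$myelin["len"])
    nd <- new_section(nxt(), my$id, "node", s$node["diam"], s$node["len"])
    node_ids[k] <- nd$id
    chain <- c(chain, list(my, nd))
    prev <- nd$id
  }
  my4 <- new_section(nxt(), prev, "myelin", s$myelin["diam"], s$myelin["len"])
  col1 <- new_section(nxt(), node_ids[2], "collateral",
                      s$collateral["diam"], s$collateral["len"])
  col2 <- new_section(nxt(), col1$id, "collateral",
                      s$collateral["diam"], s$collateral["len"])
  out <- do.call(rbind, c(chain, list(my4, col1, col2)))
  rownames(out) <- NULL
  out
}

#' Generate a surrogate dendritic tree
#'
#' Builds a seeded random tree with three branch orders (trunk attached to
#' the soma, principal, terminal) whose total membrane area equals the cell
#' target area minus the soma and axon areas.  Section diameters always lie
#' in the reference range 0.67--9.22 um and taper outward; section lengths
#' are drawn in the reference 1--10 um range and rescaled to meet the area
#' constraint (sections hitting the length cap are pinned there and the
#' remainder redistributed), so a tree with few sections trades section
#' count for section length at fixed membrane area.
#'
#' @param target_area Total cell area target, um2 (soma and axon included).
#' @param n_sections Number of dendritic sections (>= 3).
#' @param seed Integer seed; the tree is deterministic given the seed.
#' @param id_start,parent First id to assign and the id of the soma section.
#' @return Data frame of dendritic sections.
#' @export
generate_surrogate_dendrites <- function(target_area = 70000, n_sections = 1599,
                                         seed = 1, id_start = 14L,
                                         parent = 1L) {
  if (n_sections < 3) stop("n_sections must be at least 3")
  fixed <- pc_soma_area() + sum(with(pc_build_axon(), pi * diam * length))
  dend_target <- target_area - fixed
  if (dend_target <= 0) stop("target_area must exceed the soma + axon area")
  max_len <- 600 # hard cap on rescaled section length, um
  if (n_sections * pi * 9.22 * max_len < dend_target)
    stop("infeasible target: ", n_sections,
         " sections cannot reach the requested area within diameter limits")

  n_trunk <- max(2L, min(4L, round(0.04 * n_sections)))
  n_prin <- max(2L, round(0.18 * n_sections))
  n_term <- n_sections - n_trunk - n_prin
  if (n_term < 1L) { n_term <- 1L; n_prin <- n_sections - n_trunk - 1L }

  # seeded, deterministic; caller's RNG state is restored on exit
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  ids <- seq.int(id_start, length.out = n_sections)
  tag <- character(n_sections)
  par <- integer(n_sections)
  diam <- numeric(n_sections)

  # trunk: short unbranched chain from the soma, thick and gently tapering
  tag[1:n_trunk] <- "trunk_dendrite"
  par[1] <- parent
  if (n_trunk > 1) par[2:n_trunk] <- ids[1:(n_trunk - 1)]
  diam[1:n_trunk] <- seq(9.22, 7.5, length.out = n_trunk)

  # principal (smooth) dendrites: branch off the trunk / other principals
  pr_idx <- seq.int(n_trunk + 1L, n_trunk + n_prin)
  attach_pool <- seq_len(n_trunk) # indices into local arrays
  for (i in pr_idx) {
    host <- attach_pool[1 + (stats::runif(1) * length(attach_pool)) %/% 1]
    par[i] <- ids[host]
    diam[i] <- max(3.6, min(7.5, diam[host] * stats::runif(1, 0.55, 0.8)))
    tag[i] <- "principal_dendrite"
    attach_pool <- c(attach_pool, i)
  }

  # terminal (spiny) dendrites: thin branchlets forming chains off the
  # principal dendrites; they carry most of the membrane area and strongly
  # attenuate spike-frequency signals while staying DC-coupled
  te_idx <- seq.int(n_trunk + n_prin + 1L, n_sections)
  te_pool <- pr_idx
  for (i in te_idx) {
    host <- te_pool[1 + (stats::runif(1) * length(te_pool)) %/% 1]
    par[i] <- ids[host]
    diam[i] <- stats::runif(1, 1.1, 2.6)
    tag[i] <- "terminal_dendrite"
    te_pool <- c(te_pool, i)
  }

  # the smooth proximal core (trunk and principal dendrites) is short in
  # real Purkinje cells and keeps its drawn lengths; the spiny terminal
  # branchlets carry most of the membrane area and absorb the area rescale
  len <- stats::runif(n_sections, 1, 10)
  len[1:n_trunk] <- stats::runif(n_trunk, 8, 15)
  len[pr_idx] <- stats::runif(n_prin, 5, 15)
  core <- seq_len(n_trunk + n_prin)
  core_area <- sum(pi * diam[core] * len[core])
  # rescale terminal lengths to meet the area target; sections that would
  # exceed the length cap are pinned there and the remainder redistributed
  need <- dend_target - core_area
  raw <- len[te_idx]
  scaled <- raw
  capped <- rep(FALSE, length(raw))
  for (pass in 1:20) {
    free <- !capped
    if (!any(free)) break
    rest <- need - sum(pi * diam[te_idx][capped]) * max_len
    k <- rest / sum(pi * diam[te_idx][free] * raw[free])
    scaled[free] <- raw[free] * k
    over <- free & scaled > max_len
    if (!any(over)) break
    capped <- capped | over
    scaled[capped] <- max_len
  }
  if (any(scaled > max_len + 1e-9) || all(capped))
    stop("infeasible target: rescaled section lengths exceed ", max_len, " um")
  len[te_idx] <- scaled

  out <- data.frame(id = ids, parent = par, tag = tag, diam = diam,
                    length = len)
  attr(out, "seed") <- seed
  attr(out, "target_area") <- target_area
  out
}

pc_soma_area <- function() pi * SOMA_DIAM * SOMA_LEN

#' Assemble a full Purkinje-cell morphology
#'
#' Soma (single cylinder, 29.8 x 29.8 um), deterministic axon, and a seeded
#' surrogate dendritic tree scaled so the total cell area matches
#' `target_area`.
#'
#' @param n_dendrites Number of dendritic sections (default 400, a reduced
#'   desk-scale tree; the full-scale reference count is 1599).
#' @param seed Seed for the dendritic generator.
#' @param target_area Total cell area, um2.
#' @return An object of class `pc_morphology`: a section table with
#'   metadata attributes.
#' @export
pc_morphology <- function(n_dendrites = 400, seed = 1, target_area = 70000) {
  soma <- new_section(1L, 0L, "soma", SOMA_DIAM, SOMA_LEN)
  axon <- pc_build_axon(parent = 1L, id_start = 2L)
  dend <- generate_surrogate_dendrites(target_area, n_dendrites, seed,
                                       id_start = max(axon$id) + 1L,
                                       parent = 1L)
  m <- rbind(soma, axon, dend)
  rownames(m) <- NULL
  structure(m, class = c("pc_morphology", "data.frame"),
            seed = seed, target_area = target_area)
}

#' Total membrane area of a morphology
#'
#' Sum of the lateral cylinder areas `pi * d * L` over all sections (the
#' soma contributes its lateral cylinder area, the NEURON convention).
#'
#' @param m A `pc_morphology` or plain section table.
#' @return Area in um2.
#' @export
total_area <- function(m) sum(pi * m$diam * m$length)

#' @export
print.pc_morphology <- function(x, ...) {
  cat("Purkinje-cell morphology:", nrow(x), "sections,",
      sprintf("total area %.0f um2\n", total_area(x)))
  tab <- table(x$tag)
  for (tg in names(tab)) cat(sprintf("  %-18s %4d\n", tg, tab[tg]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# SWC exchange.  Cylinder-per-point convention: every non-root point defines
# a section from its parent point to itself.  Region tags map to SWC type
# codes: soma 1, AIS 2, trunk 5, principal 6, terminal 7, paraAIS 8,
# myelin 9, node 10, collateral 11 (types 3/4 read back as principal /
# terminal dendrites).
# ---------------------------------------------------------------------------

SWC_TYPE <- c(soma = 1, AIS = 2, trunk_dendrite = 5, principal_dendrite = 6,
              terminal_dendrite = 7, paraAIS = 8, myelin = 9, node = 10,
              collateral = 11)

#' Write a morphology to SWC
#'
#' The soma is written as two points (root plus distal end); every other
#' section becomes one point attached to its parent section's point.
#' Coordinates are synthesised along deterministic directions -- only
#' topology, diameters and lengths are meaningful.
#'
#' @param m Morphology.
#' @param path Output file.
#' @export
write_swc <- function(m, path) {
  n <- nrow(m)
  # golden-angle directions keep points distinct
  dir_for <- function(k) {
    th <- 2.399963 * k
    c(cos(th), sin(th), 0.1 * ((k %% 7) - 3))
  }
  pt_id <- integer(n) # swc point id of each section's distal point
  lines <- character(0)
  soma_row <- which(m$tag == "soma")
  xyz <- matrix(0, n, 3)
  lines <- c(lines, sprintf("1 1 0 0 0 %.6f -1", m$diam[soma_row] / 2))
  end <- c(m$length[soma_row], 0, 0)
  lines <- c(lines, sprintf("2 1 %.6f %.6f %.6f %.6f 1",
                            end[1], end[2], end[3], m$diam[soma_row] / 2))
  pt_id[soma_row] <- 2L
  xyz[soma_row, ] <- end
  nextpt <- 3L
  ord <- order(m$id)
  for (i in ord) {
    if (m$tag[i] == "soma") next
    pr <- which(m$id == m$parent[i])
    d <- dir_for(i)
    d <- d / sqrt(sum(d^2))
    p0 <- xyz[pr, ]
    p1 <- p0 + d * m$length[i]
    lines <- c(lines, sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                              nextpt, SWC_TYPE[[m$tag[i]]],
                              p1[1], p1[2], p1[3], m$diam[i] / 2, pt_id[pr]))
    pt_id[i] <- nextpt
    xyz[i, ] <- p1
    nextpt <- nextpt + 1L
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a morphology from SWC
#'
#' @param path SWC file (7 columns; `#` comments allowed).
#' @return A `pc_morphology`.
#' @export
read_swc <- function(path) {
  raw <- readLines(path)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  fields <- strsplit(trimws(raw), "\\s+")
  bad <- vapply(fields, length, 1L) != 7
  if (any(bad)) stop("malformed SWC record at line ", which(bad)[1])
  tab <- do.call(rbind, lapply(fields, as.numeric))
  if (anyNA(tab)) stop("malformed SWC record: non-numeric field")
  colnames(tab) <- c("id", "type", "x", "y", "z", "r", "parent")
  if (any(tab[, "id"] == tab[, "parent"]))
    stop("cyclic parentage: point refers to itself")
  idx <- match(tab[, "parent"], tab[, "id"])
  # cycle check by walking up
  for (i in seq_len(nrow(tab))) {
    seen <- integer(0); j <- i
    while (!is.na(j)) {
      if (j %in% seen) stop("cyclic parentage detected")
      seen <- c(seen, j)
      j <- idx[j]
    }
  }
  type_to_tag <- function(ty) {
    tg <- names(SWC_TYPE)[match(ty, SWC_TYPE)]
    tg[is.na(tg) & ty == 3] <- "principal_dendrite"
    tg[is.na(tg) & ty == 4] <- "terminal_dendrite"
    if (anyNA(tg)) stop("unknown SWC type code")
    tg
  }
  roots <- which(is.na(idx))
  if (length(roots) != 1) stop("SWC must have exactly one root point")
  soma_pts <- which(tab[, "type"] == 1)
  if (length(soma_pts) < 1) stop("SWC has no soma point")
  # soma section from root soma point(s)
  if (length(soma_pts) >= 2) {
    p0 <- tab[soma_pts[1], ]; p1 <- tab[soma_pts[2], ]
    soma_len <- sqrt(sum((p1[c("x", "y", "z")] - p0[c("x", "y", "z")])^2))
    soma_diam <- 2 * p1[["r"]]
    soma_anchor <- soma_pts[2]
  } else {
    soma_len <- 2 * tab[soma_pts[1], "r"]
    soma_diam <- 2 * tab[soma_pts[1], "r"]
    soma_anchor <- soma_pts[1]
  }
  secs <- list(new_section(1L, 0L, "soma", soma_diam, soma_len))
  sec_of_pt <- rep(NA_integer_, nrow(tab))
  sec_of_pt[soma_pts] <- 1L
  nid <- 2L
  for (i in seq_len(nrow(tab))) {
    if (tab[i, "type"] == 1) next
    pr <- idx[i]
    if (is.na(pr)) stop("non-soma root point")
    plen <- sqrt(sum((tab[i, c("x", "y", "z")] - tab[pr, c("x", "y", "z")])^2))
    secs <- c(secs, list(new_section(
      nid, sec_of_pt[pr], type_to_tag(tab[i, "type"]), 2 * tab[i, "r"], plen)))
    sec_of_pt[i] <- nid
    nid <- nid + 1L
  }
  out <- do.call(rbind, secs)
  rownames(out) <- NULL
  structure(out, class = c("pc_morphology", "data.frame"))
}

#' Drop the dendritic tree from a morphology
#'
#' Used by the dissociated-cell (dendrites severed) experiments.
#'
#' @param m Morphology.
#' @return Morphology containing only soma and axon.
#' @export
pc_remove_dendrites <- function(m) {
  keep <- !(m$tag %in% DEND_TAGS)
  out <- m[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pc_morphology", "data.frame"))
}
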