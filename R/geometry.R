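#' Proximal pulmonary vessel table
#'
#' Reference geometry of the proximal pulmonary circulation: 15 arteries (main
#' pulmonary artery down to the segmental level) and 12 veins (the four large
#' pulmonary veins draining to the left atrium plus their first daughter
#' generation). Terminal arteries are paired with terminal veins; each pair is
#' bridged by a two-sided structured-tree microvascular bed.
#'
#' @param path Optional path to a CSV with columns
#'   `name,length_cm,radius_cm,kind,parent,daughter1,daughter2,paired_terminal`.
#'   Defaults to the table packaged with `pulmtree`.
#' @return A tibble, one row per vessel.
#' @export
#' @examples
#' pulmonary_vessel_table()
pulmonary_vessel_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pulmonary_network.csv", package = "pulmtree")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  as_tibble(tab)
}

#' Build the proximal arterial-venous network
#'
#' Validates a vessel table and assembles the proximal network object: vessel
#' geometry, bifurcating connectivity on the arterial and venous sides, and the
#' terminal artery-vein pairing that defines the microvascular beds.
#'
#' Orientation convention: `x` increases in the direction of mean flow, i.e.
#' root-to-terminal in arteries and terminal-to-left-atrium in veins. Hence a
#' terminal artery couples to its bed at `x = L` and the paired terminal vein
#' at `x = 0`; the four vein roots see the left-atrial pressure at `x = L`.
#'
#' @param vessel_table A data frame as returned by [pulmonary_vessel_table()].
#' @param strict If `TRUE` (default) require exactly 15 arteries, 12 veins and
#'   8 beds; toy networks from [make_toy_network()] set this to `FALSE`.
#' @return An object of class `proximal_network`: a list with elements
#'   `vessels` (tibble with `A0_cm2` added), `root_artery`, `vein_roots`,
#'   `beds` (tibble with columns `artery`, `vein`), and `junctions`
#'   (tibble with columns `parent`, `d1`, `d2`, `type`).
#' @export
#' @examples
#' net <- build_proximal_network(pulmonary_vessel_table())
#' net
build_proximal_network <- function(vessel_table, strict = TRUE) {
  v <- as_tibble(vessel_table)
  req <- c("name", "length_cm", "radius_cm", "kind", "parent",
           "daughter1", "daughter2", "paired_terminal")
  missing_cols <- setdiff(req, names(v))
  if (length(missing_cols) > 0) {
    abort(paste0("vessel table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(v$name)) {
    abort(paste0("duplicate vessel names: ",
                 paste(unique(v$name[duplicated(v$name)]), collapse = ", ")))
  }
  if (any(!is.finite(v$length_cm)) || any(v$length_cm <= 0)) {
    abort("all vessel lengths must be positive")
  }
  if (any(!is.finite(v$radius_cm)) || any(v$radius_cm <= 0)) {
    abort("all vessel radii must be positive")
  }
  if (!all(v$kind %in% c("artery", "vein"))) {
    abort("vessel kind must be 'artery' or 'vein'")
  }
  refs <- c(v$daughter1, v$daughter2, v$parent, v$paired_terminal)
  refs <- refs[!is.na(refs) & nzchar(refs)]
  unknown <- setdiff(refs, v$name)
  if (length(unknown) > 0) {
    abort(paste0("vessels referenced but not defined: ",
                 paste(unique(unknown), collapse = ", ")))
  }

  has_d1 <- !is.na(v$daughter1) & nzchar(v$daughter1)
  has_d2 <- !is.na(v$daughter2) & nzchar(v$daughter2)
  has_pair <- !is.na(v$paired_terminal) & nzchar(v$paired_terminal)
  if (any(has_d1 != has_d2)) {
    abort("every junction must have exactly 2 daughters")
  }
  if (any(has_d1 & has_pair)) {
    abort("a vessel cannot both bifurcate and be a paired terminal")
  }
  if (any(!has_d1 & !has_pair)) {
    abort("terminal vessels must name their paired counterpart")
  }

  # pairing must be mutual and cross arterial/venous sides
  pair_of <- setNames(v$paired_terminal, v$name)
  for (nm in v$name[has_pair]) {
    other <- pair_of[[nm]]
    if (is.na(pair_of[[other]]) || pair_of[[other]] != nm) {
      abort(paste0("terminal pairing is not mutual for ", nm))
    }
    if (v$kind[v$name == nm] == v$kind[v$name == other]) {
      abort(paste0("paired terminals must be one artery and one vein: ", nm))
    }
  }

  # acyclicity: follow parent links up; each chain must reach a root
  idx <- setNames(seq_len(nrow(v)), v$name)
  for (nm in v$name) {
    seen <- character(0)
    cur <- nm
    while (!is.na(v$parent[idx[[cur]]]) && nzchar(v$parent[idx[[cur]]])) {
      if (cur %in% seen) abort("connectivity contains a cycle")
      seen <- c(seen, cur)
      cur <- v$parent[idx[[cur]]]
    }
  }

  v$A0_cm2 <- pi * v$radius_cm^2

  arteries <- v$name[v$kind == "artery"]
  veins <- v$name[v$kind == "vein"]
  roots_a <- v$name[v$kind == "artery" & (is.na(v$parent) | !nzchar(v$parent))]
  roots_v <- v$name[v$kind == "vein" & (is.na(v$parent) | !nzchar(v$parent))]
  if (length(roots_a) != 1) abort("network must have exactly one arterial root")

  beds <- tibble(
    artery = v$name[has_pair & v$kind == "artery"],
    vein = pair_of[v$name[has_pair & v$kind == "artery"]]
  )

  junctions <- dplyr::bind_rows(
    tibble(parent = v$name[has_d1 & v$kind == "artery"],
           d1 = v$daughter1[has_d1 & v$kind == "artery"],
           d2 = v$daughter2[has_d1 & v$kind == "artery"],
           type = "diverging"),
    # venous "daughters" lie upstream of the vein root: flow converges into it
    tibble(parent = v$name[has_d1 & v$kind == "vein"],
           d1 = v$daughter1[has_d1 & v$kind == "vein"],
           d2 = v$daughter2[has_d1 & v$kind == "vein"],
           type = "converging")
  )

  if (strict) {
    if (length(arteries) != 15 || length(veins) != 12) {
      abort(sprintf("expected 15 arteries and 12 veins, got %d and %d",
                    length(arteries), length(veins)))
    }
    if (nrow(beds) != 8) abort("expected 8 microvascular beds")
    if (length(roots_v) != 4) abort("expected 4 vein roots")
  }

  structure(
    list(vessels = v, root_artery = roots_a, vein_roots = roots_v,
         beds = beds, junctions = junctions),
    class = "proximal_network"
  )
}

#' @export
print.proximal_network <- function(x, ...) {
  na <- sum(x$vessels$kind == "artery")
  nv <- sum(x$vessels$kind == "vein")
  cat(sprintf("<proximal_network> %d arteries, %d veins, %d beds; root %s\n",
              na, nv, nrow(x$beds), x$root_artery))
  invisible(x)
}

#' @export
tidy.proximal_network <- function(x, ...) x$vessels

#' Generate a structured-tree specification
#'
#' Builds the self-similar bifurcating tree of distal vessels rooted at a
#' terminal proximal vessel. A node at generation indices `(i, j)` has radius
#' `r_ij = alpha^i * beta^j * root_radius` and length `L_ij = r_ij * lrr`,
#' where `alpha` and `beta` are the major and minor daughter radius scaling
#' factors and `lrr` the length-to-radius ratio. A node belongs to the tree iff
#' its radius is at least `r_min` (the cutoff where the arterial and venous
#' beds meet); a node is terminal iff both daughters fall below the cutoff.
#' When only the minor (`beta`) daughter falls below `r_min` it is pruned and
#' the branch continues through the major daughter alone.
#'
#' @param root_radius Root radius in cm.
#' @param alpha,beta Radius scaling factors, `0 < beta < alpha < 1`.
#' @param lrr Length-to-radius ratio (dimensionless).
#' @param r_min Minimum radius cutoff in cm.
#' @return An object of class `structured_tree`: a list with a `nodes` tibble
#'   (`i`, `j`, `radius_cm`, `length_cm`, `has_alpha`, `has_beta`, `terminal`)
#'   and the generating parameters as fields.
#' @export
#' @examples
#' generate_tree(0.5, alpha = 0.88, beta = 0.66, lrr = 25, r_min = 0.01)
generate_tree <- function(root_radius, alpha, beta, lrr, r_min) {
  if (!is.finite(root_radius) || root_radius <= 0) abort("root_radius must be positive")
  if (!is.finite(r_min) || r_min <= 0) abort("r_min must be positive")
  if (!(beta > 0 && alpha > beta && alpha < 1)) {
    abort("need 0 < beta < alpha < 1")
  }
  if (lrr <= 0) abort("lrr must be positive")

  if (r_min > root_radius) {
    # degenerate: the root itself is below the cutoff region boundary -> depth 0
    nodes <- tibble(i = 0L, j = 0L, radius_cm = root_radius,
                    length_cm = root_radius * lrr,
                    has_alpha = FALSE, has_beta = FALSE, terminal = TRUE)
    return(structure(list(nodes = nodes, root_radius = root_radius,
                          alpha = alpha, beta = beta, lrr = lrr, r_min = r_min),
                     class = "structured_tree"))
  }

  # all (i, j) with alpha^i beta^j root >= r_min: lattice region under a line
  lim <- log(r_min / root_radius)  # <= 0
  la <- log(alpha); lb <- log(beta)
  i_max <- floor(lim / la + 1e-12)
  rows <- vector("list", i_max + 1L)
  for (i in 0:i_max) {
    j_max <- floor((lim - i * la) / lb + 1e-12)
    j <- 0:j_max
    r <- root_radius * alpha^i * beta^j
    rows[[i + 1L]] <- tibble(i = i, j = j, radius_cm = r)
  }
  nodes <- dplyr::bind_rows(rows)
  nodes$length_cm <- nodes$radius_cm * lrr
  key <- paste(nodes$i, nodes$j)
  in_tree <- function(ii, jj) paste(ii, jj) %in% key
  nodes$has_alpha <- in_tree(nodes$i + 1L, nodes$j)
  nodes$has_beta <- in_tree(nodes$i, nodes$j + 1L)
  nodes$terminal <- !nodes$has_alpha & !nodes$has_beta
  # alpha scales less than beta, so a surviving beta daughter implies a
  # surviving alpha daughter
  stopifnot(all(nodes$has_alpha | !nodes$has_beta))

  structure(
    list(nodes = nodes, root_radius = root_radius, alpha = alpha, beta = beta,
         lrr = lrr, r_min = r_min),
    class = "structured_tree"
  )
}

#' @export
print.structured_tree <- function(x, ...) {
  cat(sprintf(paste0("<structured_tree> root %.4g cm, alpha %.3g, beta %.3g, ",
                     "lrr %.3g, r_min %.4g cm: %d unique branches, ",
                     "max generation %d\n"),
              x$root_radius, x$alpha, x$beta, x$lrr, x$r_min,
              nrow(x$nodes), max(x$nodes$i + x$nodes$j)))
  invisible(x)
}

#' @export
tidy.structured_tree <- function(x, ...) x$nodes

#' Count the distinct self-similar subtrees of a structured tree
#'
#' Every node sharing generation indices `(i, j)` heads an identical subtree,
#' so the number of distinct `(i, j)` pairs bounds the work of the memoized
#' admittance recursion, even though the literal tree has exponentially many
#' branches.
#'
#' @param spec A `structured_tree`.
#' @return Integer count of distinct `(i, j)` index pairs.
#' @export
count_unique_subtrees <- function(spec) {
  stopifnot(inherits(spec, "structured_tree"))
  nrow(spec$nodes)
}

#' Total number of branches in the literal (un-collapsed) structured tree
#'
#' The multiplicity of index pair `(i, j)` in a full binary tree is
#' `choose(i + j, i)`; pruned minor daughters reduce this, so the count is
#' obtained by propagating path multiplicities through the lattice.
#'
#' @param spec A `structured_tree`.
#' @return Number of branches the expanded tree would contain.
#' @export
count_total_branches <- function(spec) {
  stopifnot(inherits(spec, "structured_tree"))
  nd <- spec$nodes
  mult <- setNames(rep(0, nrow(nd)), paste(nd$i, nd$j))
  mult["0 0"] <- 1
  ord <- order(nd$i + nd$j)
  for (k in ord) {
    key <- paste(nd$i[k], nd$j[k])
    m <- mult[[key]]
    if (m == 0) next
    if (nd$has_alpha[k]) {
      ka <- paste(nd$i[k] + 1L, nd$j[k])
      mult[ka] <- mult[[ka]] + m
    }
    if (nd$has_beta[k]) {
      kb <- paste(nd$i[k], nd$j[k] + 1L)
      mult[kb] <- mult[[kb]] + m
    }
  }
  sum(mult)
}

#' Mirror a structured tree onto the venous side
#'
#' The venous half of a two-sided bed shares the topology (the `(i, j)` index
#' set) of its arterial tree; radii are scaled by the ratio of the venous to
#' the arterial root radius and lengths use the venous length-to-radius ratio.
#' Each arterial terminal joins its mirrored venous terminal.
#'
#' @param arterial_tree A `structured_tree` for the arterial side.
#' @param root_radius_vein Venous root radius (cm).
#' @param lrr_vein Venous length-to-radius ratio.
#' @return A `structured_tree` with the same index set.
#' @export
mirror_tree <- function(arterial_tree, root_radius_vein, lrr_vein) {
  stopifnot(inherits(arterial_tree, "structured_tree"))
  if (root_radius_vein <= 0) abort("venous root radius must be positive")
  scale <- root_radius_vein / arterial_tree$root_radius
  nodes <- arterial_tree$nodes
  nodes$radius_cm <- nodes$radius_cm * scale
  nodes$length_cm <- nodes$radius_cm * lrr_vein
  structure(
    list(nodes = nodes, root_radius = root_radius_vein,
         alpha = arterial_tree$alpha, beta = arterial_tree$beta,
         lrr = lrr_vein, r_min = arterial_tree$r_min * scale),
    class = "structured_tree"
  )
}
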