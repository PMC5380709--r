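#' Molecular geometry
#'
#' An ordered list of atoms with element symbols, atomic masses (amu) and
#' Cartesian coordinates (Angstrom), with optional PDB-style labels and
#' per-atom partial charges.  All pairwise operations (distances, topology
#' diffs, biased-pair searches) require two geometries to be *conformable*:
#' same length and same element sequence.  No atom matching or reordering is
#' ever attempted; endpoint structures are assumed consistently ordered.
#'
#' @param element character vector of element symbols.
#' @param xyz numeric n x 3 matrix of Cartesian coordinates in Angstrom.
#' @param mass optional numeric vector of masses in amu; defaults to the
#'   most-abundant-isotope mass of each element.
#' @param labels optional data.frame with one row per atom; conventional
#'   columns are `resname`, `resid`, `atom`, `icode`, `rectype`.
#' @param charge optional numeric vector of per-atom partial charges (e).
#' @return an object of class `geometry`.
#' @export
geometry <- function(element, xyz, mass = NULL, labels = NULL, charge = NULL) {
  element <- as.character(element)
  n <- length(element)
  if (n < 1L) stop("a geometry needs at least one atom")
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  if (nrow(xyz) != n) {
    stop("coordinate rows (", nrow(xyz), ") != number of atoms (", n, ")")
  }
  if (is.null(mass)) mass <- atomic_mass(element)
  mass <- as.numeric(mass)
  if (length(mass) != n || any(!is.finite(mass)) || any(mass <= 0)) {
    stop("masses must be ", n, " positive finite numbers")
  }
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    if (nrow(labels) != n) stop("labels must have one row per atom")
  }
  if (!is.null(charge)) {
    charge <- as.numeric(charge)
    if (length(charge) != n) stop("charge must have one value per atom")
  }
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(element = element, mass = mass, xyz = xyz,
                 labels = labels, charge = charge),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat("geometry:", n_atoms(x), "atoms (",
      paste(utils::head(x$element, 8L), collapse = " "),
      if (n_atoms(x) > 8L) "..." else "", ")\n")
  invisible(x)
}

#' Number of atoms in a geometry
#' @param g a `geometry`.
#' @return integer atom count.
#' @export
n_atoms <- function(g) length(g$element)

is_geometry <- function(g) inherits(g, "geometry")

#' Test whether two geometries are conformable
#'
#' Conformable means same atom count and identical element sequence.
#'
#' @param a,b `geometry` objects.
#' @return logical.
#' @export
conformable <- function(a, b) {
  n_atoms(a) == n_atoms(b) && all(a$element == b$element)
}

stop_if_not_conformable <- function(a, b) {
  if (!conformable(a, b)) {
    stop("geometries are not conformable (atom counts or element ",
         "sequences differ)")
  }
  invisible(TRUE)
}

#' Replace the coordinates of a geometry
#' @param g a `geometry`.
#' @param xyz n x 3 coordinate matrix or length-3n vector.
#' @return the geometry with new coordinates.
#' @export
set_coords <- function(g, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  if (nrow(xyz) != n_atoms(g)) stop("coordinate rows != atom count")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  g$xyz <- xyz
  g
}

#' Euclidean distance between two geometries on the Cartesian PES
#'
#' The root of the summed squared Cartesian coordinate differences over all
#' atoms.  Distances on the potential energy surface are deliberately *not*
#' mass-weighted; mass-weighting is applied only when intrinsic reaction
#' coordinate paths are generated (see [follow_irc()]).
#'
#' @param a,b conformable `geometry` objects.
#' @return distance in Angstrom.
#' @export
pes_distance <- function(a, b) {
  stop_if_not_conformable(a, b)
  sqrt(sum((a$xyz - b$xyz)^2))
}

#' Contained angle at a point on the Cartesian PES from three distances
#'
#' Law-of-cosines angle at vertex B of the triangle with side lengths
#' `d_ab`, `d_bc` and `d_ac`.  Used to characterize the shape of a reaction
#' path from the PES distances between a transition state and its flanking
#' stationary points (an angle near 180 degrees indicates a straight path).
#'
#' @param d_ab,d_bc,d_ac pairwise PES distances in Angstrom, all positive.
#' @param tol relative slack allowed on the triangle inequality.
#' @return angle at vertex B in degrees, in (0, 180].
#' @export
contained_angle <- function(d_ab, d_bc, d_ac, tol = 1e-8) {
  if (any(c(d_ab, d_bc, d_ac) <= 0)) stop("distances must be positive")
  if (d_ac > (d_ab + d_bc) * (1 + tol)) {
    stop("triangle inequality violated: d_ac > d_ab + d_bc")
  }
  cosb <- (d_ab^2 + d_bc^2 - d_ac^2) / (2 * d_ab * d_bc)
  cosb <- min(1, max(-1, cosb))
  acos(cosb) * 180 / pi
}

#' Infer covalent topology from interatomic distances
#'
#' Atoms i and j are bonded iff their separation is at most
#' `scale * (r_cov(i) + r_cov(j))`.  The bond-detection criterion is a
#' standard covalent-radius heuristic; 1.2 is the conventional scale.
#'
#' @param g a `geometry`.
#' @param scale dimensionless threshold multiplier (> 0).
#' @return an object of class `topology`: list with `n_atoms`, `bonds`
#'   (m x 2 integer matrix, i < j) and `degree` (per-atom bond count).
#' @export
infer_topology <- function(g, scale = 1.2) {
  if (scale <= 0) stop("scale must be positive")
  n <- n_atoms(g)
  r <- covalent_radius(g$element)
  bonds <- matrix(integer(0), ncol = 2L)
  if (n > 1L) {
    d <- as.matrix(stats::dist(g$xyz))
    thr <- outer(r, r, `+`) * scale
    hit <- which(d <= thr & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit)) bonds <- unname(cbind(hit[, 1L], hit[, 2L]))
  }
  storage.mode(bonds) <- "integer"
  degree <- tabulate(c(bonds), nbins = n)
  structure(list(n_atoms = n, bonds = bonds, degree = degree),
            class = "topology")
}

# per-atom bond partner sets of a topology
.partners <- function(topo) {
  p <- vector("list", topo$n_atoms)
  for (k in seq_len(nrow(topo$bonds))) {
    i <- topo$bonds[k, 1L]; j <- topo$bonds[k, 2L]
    p[[i]] <- c(p[[i]], j); p[[j]] <- c(p[[j]], i)
  }
  lapply(p, function(v) sort(unique(v)))
}

#' Atoms whose connectivity differs between two topologies
#'
#' Comparing the covalent topologies of a reaction's two endpoint
#' structures identifies the atoms involved in bond making and breaking;
#' for simple reactions such as a proton transfer this set normally holds
#' 2 to 4 atoms, and it seeds the active set of [refine_saddle()].
#'
#' @param topo_a,topo_g `topology` objects over the same atom count.
#' @param include_neighbors if `TRUE`, also include every atom bonded (in
#'   either topology) to a changed atom.  Enlarging the set improves the
#'   refinement at extra cost; off by default.
#' @return sorted integer vector of atom indices.
#' @export
diff_topology <- function(topo_a, topo_g, include_neighbors = FALSE) {
  if (topo_a$n_atoms != topo_g$n_atoms) {
    stop("topologies cover different atom counts")
  }
  pa <- .partners(topo_a); pg <- .partners(topo_g)
  changed <- which(vapply(seq_len(topo_a$n_atoms),
                          function(i) !identical(pa[[i]], pg[[i]]),
                          logical(1)))
  if (include_neighbors && length(changed)) {
    nb <- unlist(c(pa[changed], pg[changed]), use.names = FALSE)
    changed <- sort(unique(c(changed, nb)))
  }
  as.integer(changed)
}

#' Mutation specification for charge-neutralization experiments
#'
#' Describes the in-silico mutations used to switch off a charged site so
#' that thermodynamic-cycle double differences can isolate one
#' interaction's energy:
#' \describe{
#'   \item{`delete-H-and-promote-donor`}{remove a donor hydrogen and
#'     replace the donor by the element one atomic number higher (N to O,
#'     O to F), deleting a hydrogen bond without leaving a radical.}
#'   \item{`sidechain-replacement`}{replace a set of side-chain atoms by a
#'     single atom of `replacement` element (e.g. carboxylate to H for an
#'     Asp-to-Ala mutation).}
#'   \item{`proton-deletion`}{remove an acidic proton, decrementing the
#'     formal charge.}
#' }
#'
#' @param kind one of the three mutation kinds above.
#' @param target integer indices of the atoms operated on.  For
#'   `delete-H-and-promote-donor`, `target[1]` is the hydrogen and
#'   `target[2]` the donor atom.
#' @param replacement element symbol for `sidechain-replacement`.
#' @return an object of class `mutation_spec`.
#' @export
mutation_spec <- function(kind = c("delete-H-and-promote-donor",
                                   "sidechain-replacement",
                                   "proton-deletion"),
                          target, replacement = NULL) {
  kind <- match.arg(kind)
  target <- as.integer(target)
  if (!length(target)) stop("mutation needs target atoms")
  if (kind == "sidechain-replacement" && is.null(replacement)) {
    stop("sidechain-replacement needs a replacement element")
  }
  structure(list(kind = kind, target = target, replacement = replacement),
            class = "mutation_spec")
}

#' Apply a neutralization mutation to a geometry
#'
#' Edits a geometry according to a [mutation_spec()].  Every atom not named
#' in the spec keeps bit-identical coordinates, so that heats of formation
#' of mutant and native systems remain directly comparable when most of the
#' system is held frozen; only the mutated site itself is expected to be
#' re-optimized afterwards.
#'
#' @param g a `geometry`.
#' @param spec a `mutation_spec`.
#' @param scale covalent-radius scale used to verify that a deleted
#'   hydrogen is actually bonded to its donor.
#' @return the edited `geometry`, with attribute `charge_delta` giving the
#'   formal-charge bookkeeping change (e).
#' @export
mutate_for_neutralization <- function(g, spec, scale = 1.2) {
  stopifnot(inherits(spec, "mutation_spec"))
  if (any(spec$target < 1L | spec$target > n_atoms(g))) {
    stop("mutation target atoms out of range")
  }
  drop_atoms <- function(g, idx) {
    keep <- setdiff(seq_len(n_atoms(g)), idx)
    geometry(g$element[keep], g$xyz[keep, , drop = FALSE],
             mass = g$mass[keep],
             labels = if (!is.null(g$labels)) g$labels[keep, , drop = FALSE],
             charge = g$charge[keep])
  }
  if (spec$kind == "delete-H-and-promote-donor") {
    h <- spec$target[1L]; donor <- spec$target[2L]
    if (is.na(donor)) stop("spec must name the hydrogen and its donor")
    if (g$element[h] != "H") stop("target atom ", h, " is not a hydrogen")
    dist_hd <- sqrt(sum((g$xyz[h, ] - g$xyz[donor, ])^2))
    if (dist_hd > scale * sum(covalent_radius(g$element[c(h, donor)]))) {
      stop("target H is not bonded to the named donor atom")
    }
    promoted <- .next_element(g$element[donor])
    g$element[donor] <- promoted
    g$mass[donor] <- atomic_mass(promoted)
    out <- drop_atoms(g, h)
    attr(out, "charge_delta") <- 0
  } else if (spec$kind == "proton-deletion") {
    if (any(g$element[spec$target] != "H")) {
      stop("proton-deletion targets must be hydrogens")
    }
    out <- drop_atoms(g, spec$target)
    attr(out, "charge_delta") <- -length(spec$target)
  } else { # sidechain-replacement
    keep_one <- spec$target[1L]
    g$element[keep_one] <- spec$replacement
    g$mass[keep_one] <- atomic_mass(spec$replacement)
    out <- drop_atoms(g, spec$target[-1L])
    attr(out, "charge_delta") <- 0
  }
  out
}
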