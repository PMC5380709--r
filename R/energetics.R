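#' Heat-of-formation table
#'
#' Labeled heats of formation for the named systems of a catalytic cycle
#' or a thermodynamic mutation cycle.  Columns: `id` (unique), optional
#' `description`, `charge` (net charge, e), `dhf` (kcal/mol), `role`
#' (`"intermediate"`, `"transition_state"` or `"mutant_system"`), and for
#' transition states `reactant_id` / `product_id` naming the flanking
#' intermediates.
#'
#' @param df data.frame with the columns above.
#' @return object of classes `heat_table` and `data.frame`.
#' @export
heat_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("id", "dhf", "role")
  if (!all(need %in% names(df))) {
    stop("heat table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$id)) stop("heat table ids must be unique")
  ts <- df$role == "transition_state"
  if (any(ts)) {
    if (!all(c("reactant_id", "product_id") %in% names(df)) ||
        any(!nzchar(df$reactant_id[ts])) || any(!nzchar(df$product_id[ts]))) {
      stop("every transition_state record must name reactant_id and ",
           "product_id")
    }
  }
  class(df) <- c("heat_table", "data.frame")
  df
}

#' Read a heat table from CSV
#' @param path CSV with the [heat_table()] columns.
#' @return a `heat_table`.
#' @export
read_heat_table <- function(path) {
  heat_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

.dhf_of <- function(table, id) {
  i <- match(id, table$id)
  if (anyNA(i)) {
    stop("system id(s) not in heat table: ",
         paste(id[is.na(i)], collapse = ", "))
  }
  table$dhf[i]
}

#' Shift a heat table relative to a reference system
#'
#' Standard heats of formation of protein-sized systems are very large
#' and negative; reporting them relative to one reference state (here,
#' conventionally the first intermediate of the cycle) keeps the numbers
#' readable.  The operation is idempotent and shift-invariant.
#'
#' @param table a [heat_table()].
#' @param ref id of the reference system (maps to 0).
#' @return the shifted `heat_table`.
#' @export
relative_energies <- function(table, ref) {
  shift <- .dhf_of(table, ref)
  table$dhf <- table$dhf - shift
  table
}

#' Barrier heights from a heat table
#'
#' For every transition-state record, the barrier is its heat of
#' formation minus that of its reactant intermediate, in the declared
#' reaction direction.
#'
#' @param table a [heat_table()].
#' @return data.frame with `reaction`, `ts_id` and `barrier` (kcal/mol);
#'   negative barriers are flagged with a warning (a transition state
#'   below its reactant indicates mislabeled records).
#' @export
barrier_heights <- function(table) {
  ts <- table[table$role == "transition_state", , drop = FALSE]
  barrier <- ts$dhf - .dhf_of(table, ts$reactant_id)
  if (any(barrier < 0)) {
    warning("negative barrier for ", paste(
      ts$id[barrier < 0], collapse = ", "),
      ": transition state below its reactant")
  }
  data.frame(reaction = paste(ts$reactant_id, "->", ts$product_id),
             ts_id = ts$id, barrier = barrier,
             stringsAsFactors = FALSE)
}

#' Electrostatic interaction energy by a four-system thermodynamic cycle
#'
#' Given two charged sites, four systems are modeled: both sites ionized
#' (A), only the second (B), only the first (C), and neither (D).  The
#' interaction energy is the double difference
#' `E = dHf(A) + dHf(D) - (dHf(B) + dHf(C))`: every contribution except
#' the site-site electrostatic interaction cancels.  The result is
#' invariant under swapping the roles of the two sites (which exchanges B
#' and C).
#'
#' @param h_a,h_b,h_c,h_d heats of formation (kcal/mol) of the four
#'   systems in the A/B/C/D pattern above.
#' @return interaction energy in kcal/mol.
#' @export
electrostatic_interaction <- function(h_a, h_b, h_c, h_d) {
  h_a + h_d - (h_b + h_c)
}

#' Change in a hydrogen bond's energy between two states
#'
#' Four systems: states A and B with the hydrogen bond present (`H(A)`,
#' `H(B)`) and with it deleted by mutating the donor (`X(A)`, `X(B)`).
#' The change in hydrogen-bond energy from A to B is
#' `(dHf(H(B)) - dHf(H(A))) - (dHf(X(B)) - dHf(X(A)))`.
#' A mutation with no differential effect gives exactly zero.
#'
#' @param h_ha,h_hb,h_xa,h_xb heats of formation (kcal/mol) in the
#'   H(A)/H(B)/X(A)/X(B) pattern.
#' @return energy change in kcal/mol.
#' @export
hbond_energy_change <- function(h_ha, h_hb, h_xa, h_xb) {
  (h_hb - h_ha) - (h_xb - h_xa)
}

#' Net effect of a mutation on a reaction step
#'
#' The double difference
#' `(dHf(mutant_b) - dHf(mutant_a)) - (dHf(native_b) - dHf(native_a))`:
#' how much the mutation changes the relative heat of formation of state
#' b with respect to state a.
#'
#' @param table a [heat_table()].
#' @param native_a,native_b,mutant_a,mutant_b system ids.
#' @return energy change in kcal/mol.
#' @export
mutation_delta <- function(table, native_a, native_b, mutant_a, mutant_b) {
  (.dhf_of(table, mutant_b) - .dhf_of(table, mutant_a)) -
    (.dhf_of(table, native_b) - .dhf_of(table, native_a))
}

#' Audit the net charge change at a site
#'
#' Sums per-residue partial-charge changes over all residues tagged with
#' a site.  Used to confirm that a formal charge separation (e.g. +1 on a
#' histidinium site, -1 on an oxyanion site) is reflected in the
#' computed partial charges.
#'
#' @param deltas data.frame with columns `residue`, `site` (tag:
#'   `"cationic"`, `"oxyanion"`, `"other"`) and `delta` (e).
#' @param site site tag to audit.
#' @return net charge change in e (0 with a warning for an empty site).
#' @export
charge_audit <- function(deltas, site) {
  if (!all(c("residue", "site", "delta") %in% names(deltas))) {
    stop("charge delta table needs columns residue, site, delta")
  }
  rows <- deltas$site == site
  if (!any(rows)) {
    warning("no residues tagged with site '", site, "'")
    return(0)
  }
  sum(deltas$delta[rows])
}

#' Evaluate every four-system electrostatic cycle in a systems table
#'
#' @param systems data.frame with columns `cycle`, `system` (letters
#'   A/B/C/D), `dhf`, and optionally `step` to select one column of a
#'   multi-step block.
#' @param step optional step filter.
#' @return data.frame with `cycle` and `energy` (kcal/mol).
#' @export
electrostatic_cycles <- function(systems, step = NULL) {
  if (!is.null(step) && "step" %in% names(systems)) {
    systems <- systems[systems$step == step, , drop = FALSE]
  }
  out <- lapply(split(systems, systems$cycle), function(blk) {
    v <- stats::setNames(blk$dhf, blk$system)
    if (!all(c("A", "B", "C", "D") %in% names(v))) {
      stop("cycle '", blk$cycle[1L], "' lacks one of systems A-D")
    }
    data.frame(cycle = blk$cycle[1L],
               energy = electrostatic_interaction(v["A"], v["B"],
                                                  v["C"], v["D"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Evaluate every hydrogen-bond cycle in a systems table
#'
#' @param systems data.frame with columns `bond`, `system` (one of
#'   H_A/H_B/X_A/X_B) and `dhf`.
#' @return data.frame with `bond` and `energy_change` (kcal/mol).
#' @export
hbond_cycles <- function(systems) {
  out <- lapply(split(systems, systems$bond), function(blk) {
    v <- stats::setNames(blk$dhf, blk$system)
    if (!all(c("H_A", "H_B", "X_A", "X_B") %in% names(v))) {
      stop("bond '", blk$bond[1L], "' lacks one of H_A/H_B/X_A/X_B")
    }
    data.frame(bond = blk$bond[1L],
               energy_change = hbond_energy_change(v["H_A"], v["H_B"],
                                                   v["X_A"], v["X_B"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Full energetics report for a catalytic cycle
#'
#' Bundles the relative energy diagram, barrier list, electrostatic and
#' hydrogen-bond cycle results, and charge audits into one list, suitable
#' for JSON serialization.
#'
#' @param heats a [heat_table()] (relative energies).
#' @param electro optional electrostatic systems table
#'   (see [electrostatic_cycles()]).
#' @param hbond optional hydrogen-bond systems table
#'   (see [hbond_cycles()]).
#' @param charges optional charge delta table (see [charge_audit()]).
#' @param electro_step step filter for the electrostatic table.
#' @return named list.
#' @export
cycle_report <- function(heats, electro = NULL, hbond = NULL,
                         charges = NULL, electro_step = NULL) {
  rep <- list(
    diagram = heats[, c("id", "dhf", "role")],
    barriers = barrier_heights(heats)
  )
  if (!is.null(electro)) {
    rep$electrostatic <- electrostatic_cycles(electro, step = electro_step)
  }
  if (!is.null(hbond)) rep$hydrogen_bonds <- hbond_cycles(hbond)
  if (!is.null(charges)) {
    rep$charge_audit <- data.frame(
      site = unique(charges$site),
      net_delta = vapply(unique(charges$site),
                         function(s) charge_audit(charges, s), numeric(1)))
  }
  rep
}
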