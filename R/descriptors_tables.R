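#' Metal-centered descriptors
#'
#' A pure table lookup on the free neutral atom: `cp` is the period of the
#' element, and `cs`/`cd`/`cf` the electron counts of the outermost s, d and
#' f subshells of the free-atom ground-state configuration (prior to
#' coordination; e.g. Ru is [Kr]4d7 5s1, so cs = 1, cd = 7, cf = 0).
#' `cn` (number of metal centers) and `mc` (charge of the metal center) are
#' annotations passed through from the input.
#'
#' @param symbol element symbol of the metal center, e.g. `"Ru"`
#' @param charge formal charge of the metal center (`mc`)
#' @param count number of metal centers in the complex (`cn`)
#' @return named numeric vector `cn`, `cp`, `mc`, `cf`, `cd`, `cs`
#' @examples
#' metal_descriptors("Ru", charge = 2)
#' @export
metal_descriptors <- function(symbol, charge = 0, count = 1) {
  tab <- metal_config_table()
  row <- tab[tab$symbol == symbol, ]
  if (nrow(row) != 1)
    stop(sprintf("unknown metal '%s'; supported: %s", symbol,
                 paste(tab$symbol, collapse = ", ")))
  c(cn = as.numeric(count), cp = as.numeric(row$period),
    mc = as.numeric(charge), cf = as.numeric(row$cf),
    cd = as.numeric(row$cd), cs = as.numeric(row$cs))
}

#' External-condition descriptors
#'
#' Looks up the static (`eps`) and infinite-frequency (`epsinf`) dielectric
#' constants of the solvent from the bundled table and passes the
#' irradiation wavelength through. Unknown solvents are rejected with the
#' closest bundled name as a suggestion.
#'
#' @param solvent solvent name (case-insensitive; common synonyms such as
#'   "MeCN" or "DCM" are accepted)
#' @param wavelength_nm irradiation wavelength in nm (> 0)
#' @return named numeric vector `eps`, `epsinf`, `wl`
#' @examples
#' condition_descriptors("water", 450)
#' @export
condition_descriptors <- function(solvent, wavelength_nm) {
  if (!is.finite(wavelength_nm) || wavelength_nm <= 0)
    stop("irradiation wavelength must be positive")
  key <- gsub("[ -]", "_", tolower(trimws(solvent)))
  if (key %in% names(SOLVENT_SYNONYMS)) key <- SOLVENT_SYNONYMS[[key]]
  tab <- solvent_table()
  row <- tab[tab$solvent == key, ]
  if (nrow(row) != 1) {
    sugg <- tab$solvent[which.min(utils::adist(key, tab$solvent))]
    stop(sprintf("unknown solvent '%s'; did you mean '%s'?", solvent, sugg))
  }
  c(eps = row$eps, epsinf = row$epsinf, wl = as.numeric(wavelength_nm))
}

# ---------------------------------------------------------------------------
# annotated connection tables and substructure counting

#' Annotated connection table
#'
#' Minimal structure input for the functional-group counter: atoms with
#' element symbols, formal charges, optional implicit-hydrogen counts and
#' metal-donor flags; bonds with integer orders (1, 2, 3; 1.5 marks an
#' aromatic bond). Charge annotations `nc` (complex cation), `lc` (all
#' ligands) and `mc` (metal center) must be supplied; `cc` (charge of the
#' atoms bound to the metal) defaults to the summed formal charges of the
#' atoms flagged `metal_donor`.
#'
#' @param atoms data frame with columns `element` and optionally `charge`,
#'   `hydrogens`, `metal_donor`
#' @param bonds data frame with columns `a`, `b` (1-based atom indices) and
#'   `order`
#' @param nc,lc,mc integer charge annotations
#' @param cc optional override of the donor-atom charge sum
#' @return a `connection_table`
#' @export
connection_table <- function(atoms, bonds = NULL, nc = 0, lc = 0, mc = 0,
                             cc = NULL) {
  atoms <- as.data.frame(atoms)
  if (!"element" %in% names(atoms)) stop("atoms need an 'element' column")
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$hydrogens)) atoms$hydrogens <- 0
  if (is.null(atoms$metal_donor)) atoms$metal_donor <- FALSE
  if (any(is.na(atoms$charge)))
    stop("missing formal-charge annotation on atoms")
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0) {
    bonds <- data.frame(a = integer(), b = integer(), order = numeric())
  } else {
    bonds <- as.data.frame(bonds)
    stopifnot(all(c("a", "b") %in% names(bonds)))
    if (is.null(bonds$order)) bonds$order <- NA_real_
    if (any(bonds$a < 1 | bonds$a > nrow(atoms) |
            bonds$b < 1 | bonds$b > nrow(atoms)))
      stop("bond references an atom index outside the table")
  }
  if (is.null(cc)) cc <- sum(atoms$charge[atoms$metal_donor])
  structure(list(atoms = atoms, bonds = bonds,
                 nc = nc, lc = lc, cc = cc, mc = mc),
            class = "connection_table")
}

# approximate smallest set of smallest rings: candidate cycles from
# per-edge shortest paths, then a GF(2)-independent subset of the
# cycle-space dimension, smallest first
perceive_rings <- function(ct) {
  nb <- nrow(ct$bonds)
  nv <- nrow(ct$atoms)
  if (nb == 0) return(list())
  g <- igraph::graph_from_edgelist(as.matrix(ct$bonds[, c("a", "b")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < nv) g <- igraph::add_vertices(g, nv - igraph::vcount(g))
  ncyc <- nb - nv + igraph::count_components(g)
  if (ncyc <= 0) return(list())
  cand <- list()
  for (e in seq_len(nb)) {
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = ct$bonds$a[e], to = ct$bonds$b[e]))
    p <- as.integer(sp$vpath[[1]])
    if (length(p) >= 3) cand[[length(cand) + 1]] <- sort(p)
  }
  if (length(cand) == 0) return(list())
  cand <- unique(cand)
  cand <- cand[order(lengths(cand))]
  # GF(2) independence over edge-incidence vectors
  edge_key <- paste(pmin(ct$bonds$a, ct$bonds$b),
                    pmax(ct$bonds$a, ct$bonds$b))
  cyc_vec <- function(vs) {
    n <- length(vs)
    v <- logical(nb)
    for (i in seq_len(nb))
      v[i] <- ct$bonds$a[i] %in% vs && ct$bonds$b[i] %in% vs
    v
  }
  basis <- matrix(logical(0), nrow = 0, ncol = nb)
  rings <- list()
  for (cy in cand) {
    if (length(rings) >= ncyc) break
    v <- cyc_vec(cy)
    red <- v
    if (nrow(basis) > 0) {
      for (r in seq_len(nrow(basis))) {
        piv <- which(basis[r, ])[1]
        if (red[piv]) red <- xor(red, basis[r, ])
      }
    }
    if (any(red)) {
      basis <- rbind(basis, red)
      rings[[length(rings) + 1]] <- cy
    }
  }
  rings
}

# hydrogen count of an atom: implicit annotation + explicit H neighbors
h_count <- function(ct, idx, adj) {
  ct$atoms$hydrogens[idx] +
    sum(ct$atoms$element[adj[[idx]]] == "H")
}

# adjacency list over all atoms
adjacency <- function(ct) {
  adj <- vector("list", nrow(ct$atoms))
  for (k in seq_len(nrow(ct$bonds))) {
    a <- ct$bonds$a[k]; b <- ct$bonds$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Molecular-structure descriptors from an annotated connection table
#'
#' Counts atoms, molecular mass, charges and the named functional groups by
#' graph matching with an explicit containment hierarchy: each carbonyl is
#' counted once, as the largest group it belongs to (amide > ester >
#' aldehyde > plain carbonyl); BODIPY cores subsume their two pyrrole rings;
#' pyridine/pyrazine/pyrrole/phenyl are ring-composition matches on the
#' smallest-ring set and require at least two ring-internal double bonds (or
#' aromatic-flagged bonds), so saturated rings are not miscounted. Raw ring
#' counts `n-r6`/`n-r5` and multiple-bond counts `n-db`/`n-tb` are taken on
#' the full graph without containment.
#'
#' Missing bond orders leave the ring-unsaturation and multiple-bond counts
#' `NA` (marked absent), never silently zero.
#'
#' @param ct a [connection_table()]
#' @return named numeric vector with the Table-2-style fields: `nc`, `lc`,
#'   `cc`, `an`, `mw` and the 19 `n-*` counts
#' @export
structure_descriptors <- function(ct) {
  stopifnot(inherits(ct, "connection_table"))
  atoms <- ct$atoms
  adj <- adjacency(ct)
  masses <- atomic_mass_table()
  unknown <- setdiff(unique(atoms$element), names(masses))
  if (length(unknown) > 0)
    stop(sprintf("no atomic mass for element(s): %s",
                 paste(unknown, collapse = ", ")))
  an <- nrow(atoms) + sum(atoms$hydrogens)
  mw <- sum(masses[atoms$element]) + sum(atoms$hydrogens) * masses[["H"]]

  orders_known <- !any(is.na(ct$bonds$order)) || nrow(ct$bonds) == 0
  ord <- ct$bonds$order
  bond_between <- function(i, j) {
    k <- which((ct$bonds$a == i & ct$bonds$b == j) |
                 (ct$bonds$a == j & ct$bonds$b == i))
    if (length(k) == 0) NA_real_ else ord[k[1]]
  }
  el <- atoms$element
  heavy_nb <- lapply(seq_along(adj), function(i)
    adj[[i]][el[adj[[i]]] != "H"])

  n_x <- sum(el %in% c("F", "Cl", "Br", "I"))
  n_s <- sum(el == "S")
  n_o <- sum(el == "O")

  n_coo <- n_co <- n_cho <- n_conh <- n_oh <- n_nh2 <- n_cn <- NA_real_
  n_db <- n_tb <- NA_real_
  amide_n <- integer(0); coo_carbonyl <- integer(0)
  if (orders_known) {
    n_db <- sum(ord == 2); n_tb <- sum(ord == 3)
    n_coo <- n_co <- n_cho <- n_conh <- 0
    # classify each carbonyl carbon once, largest group first
    for (c_idx in which(el == "C")) {
      o_dbl <- Filter(function(j) el[j] == "O" &&
                        isTRUE(bond_between(c_idx, j) == 2), adj[[c_idx]])
      if (length(o_dbl) == 0) next
      n_sing <- Filter(function(j) el[j] == "N" &&
                         isTRUE(bond_between(c_idx, j) == 1), adj[[c_idx]])
      o_sing <- Filter(function(j) el[j] == "O" &&
                         isTRUE(bond_between(c_idx, j) == 1), adj[[c_idx]])
      if (length(n_sing) > 0) {
        n_conh <- n_conh + 1
        amide_n <- c(amide_n, unlist(n_sing))
      } else if (length(o_sing) > 0) {
        n_coo <- n_coo + 1
        coo_carbonyl <- c(coo_carbonyl, c_idx)
      } else if (h_count(ct, c_idx, adj) > 0) {
        n_cho <- n_cho + 1
      } else {
        n_co <- n_co + 1
      }
    }
    n_cn <- sum(vapply(which(el == "C"), function(c_idx)
      sum(el[adj[[c_idx]]] == "N" &
            vapply(adj[[c_idx]], function(j)
              isTRUE(bond_between(c_idx, j) == 3), logical(1))),
      numeric(1)))
  }
  # hydroxyl: O with one heavy neighbor and >= 1 H, not the OH of a
  # counted ester/carboxyl group
  n_oh <- sum(vapply(which(el == "O"), function(o_idx) {
    hn <- heavy_nb[[o_idx]]
    length(hn) == 1 && h_count(ct, o_idx, adj) >= 1 &&
      !(hn[1] %in% coo_carbonyl)
  }, logical(1)))
  # primary amine: N with >= 2 H and one heavy neighbor, not an amide N
  n_nh2 <- sum(vapply(which(el == "N"), function(n_idx) {
    hn <- heavy_nb[[n_idx]]
    length(hn) == 1 && h_count(ct, n_idx, adj) >= 2 &&
      !(n_idx %in% amide_n)
  }, logical(1)))

  rings <- perceive_rings(ct)
  sizes <- lengths(rings)
  n_r6 <- sum(sizes == 6); n_r5 <- sum(sizes == 5)
  ring_unsat <- function(vs) {
    if (!orders_known) return(NA)
    k <- which((ct$bonds$a %in% vs) & (ct$bonds$b %in% vs))
    sum(ord[k] == 2) >= 2 || any(ord[k] == 1.5)
  }
  comp <- function(vs) table(factor(el[vs], levels = unique(el)))
  # bodipy: boron bearing two fluorines and bridging two N-heterocyclic
  # 5-rings; consumes those rings for the pyrrole count
  consumed <- rep(FALSE, length(rings))
  n_bodipy <- 0
  for (b_idx in which(el == "B")) {
    fs <- sum(el[adj[[b_idx]]] == "F")
    ns <- adj[[b_idx]][el[adj[[b_idx]]] == "N"]
    if (fs >= 2 && length(ns) >= 2) {
      host <- which(vapply(rings, function(vs)
        length(vs) == 5 && any(ns %in% vs), logical(1)))
      if (length(host) >= 2) {
        n_bodipy <- n_bodipy + 1
        consumed[host] <- TRUE
      }
    }
  }
  n_py <- n_ph <- n_pyra <- n_pyrr <- 0
  for (k in seq_along(rings)) {
    vs <- rings[[k]]
    uns <- ring_unsat(vs)
    if (!isTRUE(uns)) next
    cc_n <- sum(el[vs] == "C"); nn <- sum(el[vs] == "N")
    if (length(vs) == 6 && cc_n == 6) n_ph <- n_ph + 1
    if (length(vs) == 6 && cc_n == 5 && nn == 1) n_py <- n_py + 1
    if (length(vs) == 6 && cc_n == 4 && nn == 2) {
      # pyrazine: the two nitrogens sit para (graph distance 3 in the ring)
      nidx <- vs[el[vs] == "N"]
      ringadj <- lapply(vs, function(v) intersect(adj[[v]], vs))
      names(ringadj) <- vs
      d <- 0; cur <- nidx[1]; prev <- -1
      repeat {
        if (cur == nidx[2]) break
        nxt <- setdiff(ringadj[[as.character(cur)]], prev)[1]
        prev <- cur; cur <- nxt; d <- d + 1
        if (d > 6) break
      }
      if (min(d, 6 - d) == 3) n_pyra <- n_pyra + 1
    }
    if (length(vs) == 5 && cc_n == 4 && nn == 1 && !consumed[k])
      n_pyrr <- n_pyrr + 1
  }

  c(nc = as.numeric(ct$nc), lc = as.numeric(ct$lc), cc = as.numeric(ct$cc),
    an = as.numeric(an), mw = as.numeric(mw),
    `n-X` = n_x, `n-COO` = n_coo, `n-CO` = n_co, `n-CHO` = n_cho,
    `n-CONH` = n_conh, `n-OH` = as.numeric(n_oh), `n-NH2` = as.numeric(n_nh2),
    `n-S` = n_s, `n-O` = n_o, `n-CN` = n_cn,
    `n-bodipy` = as.numeric(n_bodipy), `n-py` = as.numeric(n_py),
    `n-ph` = as.numeric(n_ph), `n-pyra` = as.numeric(n_pyra),
    `n-pyrr` = as.numeric(n_pyrr), `n-r6` = as.numeric(n_r6),
    `n-r5` = as.numeric(n_r5), `n-db` = n_db, `n-tb` = n_tb)
}

#' Structure-descriptor column names
#' @return character vector (Table-2-style order)
#' @export
structure_column_names <- function() {
  c("nc", "lc", "cc", "an", "mw", "n-X", "n-COO", "n-CO", "n-CHO", "n-CONH",
    "n-OH", "n-NH2", "n-S", "n-O", "n-CN", "n-bodipy", "n-py", "n-ph",
    "n-pyra", "n-pyrr", "n-r6", "n-r5", "n-db", "n-tb")
}

# ---------------------------------------------------------------------------
# dataset preprocessing and feature assembly

#' Preprocess a measurement table
#'
#' Applies the two dataset-cleaning rules: measurements with
#' \eqn{\Phi_\Delta < 0.01} are removed, and complexes whose quantum yield
#' varies excessively across irradiation wavelengths alone (max/min ratio
#' above `wl_ratio_threshold` within a same-complex group) are removed as a
#' group. Every exclusion is logged with the rule that fired.
#'
#' @param records data frame with at least `id` (complex identifier),
#'   `phi_delta` and `wl` columns
#' @param phi_min minimum retained quantum yield
#' @param wl_ratio_threshold max/min ratio tolerated within a same-complex,
#'   different-wavelength group
#' @return list with `kept` (surviving rows) and `log` (data frame `id`,
#'   `rule`, `detail` of every excluded row)
#' @export
preprocess_dataset <- function(records, phi_min = 0.01,
                               wl_ratio_threshold = 2.0) {
  records <- as.data.frame(records)
  stopifnot(all(c("id", "phi_delta", "wl") %in% names(records)))
  log <- data.frame(id = character(), rule = character(),
                    detail = character(), stringsAsFactors = FALSE)
  low <- records$phi_delta < phi_min
  if (any(low))
    log <- rbind(log, data.frame(
      id = as.character(records$id[low]), rule = "below-threshold",
      detail = sprintf("phi_delta = %.4g < %.3g",
                       records$phi_delta[low], phi_min)))
  keep <- records[!low, , drop = FALSE]
  drop_ids <- character(0)
  for (cid in unique(keep$id)) {
    rows <- keep[keep$id == cid, , drop = FALSE]
    if (length(unique(rows$wl)) > 1) {
      ratio <- max(rows$phi_delta) / min(rows$phi_delta)
      if (ratio > wl_ratio_threshold) {
        drop_ids <- c(drop_ids, cid)
        log <- rbind(log, data.frame(
          id = as.character(rows$id), rule = "wavelength-inconsistency",
          detail = sprintf("max/min phi_delta ratio %.3g > %.3g across %d wavelengths",
                           ratio, wl_ratio_threshold, length(unique(rows$wl)))))
      }
    }
  }
  keep <- keep[!(keep$id %in% drop_ids), , drop = FALSE]
  rownames(keep) <- NULL
  list(kept = keep, log = log)
}

#' Assemble the full descriptor matrix
#'
#' Binds per-sample descriptor blocks (quantum-chemistry, structure, metal,
#' condition) into one modeling table with a fixed, documented column order,
#' the measured quantum yield as `phi_delta`, and per-block provenance in a
#' column manifest attribute.
#'
#' @param samples list of sample records; each a list with `id`, `metal`
#'   (element symbol), `source` (`"internal"` or `"external"`), `phi_delta`
#'   in (0, 1], and named numeric vectors `qcd`, `structure`, `metal_desc`,
#'   `condition`
#' @return a data frame (class `feature_table`) with attribute `manifest`
#' @export
assemble_feature_table <- function(samples) {
  blocks <- list(qcd = qcd_column_names(),
                 structure = structure_column_names(),
                 metal_desc = c("cn", "cp", "mc", "cf", "cd", "cs"),
                 condition = c("eps", "epsinf", "wl"))
  all_cols <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(all_cols))
    stop("column collision across descriptor blocks")
  rows <- lapply(samples, function(s) {
    for (b in names(blocks)) {
      missing <- setdiff(blocks[[b]], names(s[[b]]))
      if (length(missing) > 0)
        stop(sprintf("sample '%s': block '%s' is missing column(s) %s",
                     s$id, b, paste(missing, collapse = ", ")))
    }
    if (!is.numeric(s$phi_delta) || s$phi_delta <= 0 || s$phi_delta > 1)
      stop(sprintf("sample '%s': phi_delta must lie in (0, 1]", s$id))
    vals <- unlist(lapply(names(blocks),
                          function(b) as.numeric(s[[b]][blocks[[b]]])))
    c(list(id = s$id, metal = s$metal,
           source = if (is.null(s$source)) "internal" else s$source,
           phi_delta = s$phi_delta),
      stats::setNames(as.list(vals), all_cols))
  })
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  attr(tab, "manifest") <- list(
    meta = c("id", "metal", "source", "phi_delta"),
    blocks = blocks,
    units = list(spatial = "Angstrom", ee = "eV", soc = "cm^-1",
                 S1 = "nm", wl = "nm"))
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Descriptor column names of a feature table
#' @param table a `feature_table`
#' @return character vector of descriptor columns (excludes id/metal/source
#'   and the target)
#' @export
descriptor_columns <- function(table) {
  m <- attr(table, "manifest")
  if (is.null(m)) setdiff(names(table), c("id", "metal", "source", "phi_delta"))
  else unlist(m$blocks, use.names = FALSE)
}

#' Subset a feature table by metal center
#' @param table a `feature_table`
#' @param metal element symbol, e.g. `"Ru"`
#' @return feature table restricted to complexes of that metal
#' @export
subset_by_metal <- function(table, metal) {
  out <- table[table$metal == metal, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "manifest") <- attr(table, "manifest")
  class(out) <- class(table)
  out
}
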