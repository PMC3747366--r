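# Element property tables for the descriptor calculators. Masses in u,
# Sanderson electronegativities (dimensionless), van der Waals radii in
# Angstrom, Kier-Hall valence electron counts. Covers the organic subset;
# molecules with other elements are rejected at parse time.
.elem_tab <- data.frame(
  symbol  = c("H",  "B",   "C",   "N",   "O",   "F",   "Si",  "P",   "S",   "Cl",  "Br",  "I"),
  Z       = c(1,    5,     6,     7,     8,     9,     14,    15,    16,    17,    35,    53),
  Zv      = c(1,    3,     4,     5,     6,     7,     4,     5,     6,     7,     7,     7),
  mass    = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998, 28.086, 30.974, 32.06, 35.453, 79.904, 126.904),
  en      = c(2.592, 2.275, 2.746, 3.194, 3.654, 4.000, 2.138, 2.515, 2.957, 3.475, 3.219, 2.778),
  r_vdw   = c(1.17, 1.62, 1.75, 1.55, 1.40, 1.30, 1.97, 1.85, 1.80, 1.75, 1.95, 2.10),
  stringsAsFactors = FALSE)
rownames(.elem_tab) <- .elem_tab$symbol
.elem_tab$v_vdw <- 4 / 3 * pi * .elem_tab$r_vdw^3

.elem_prop <- function(sym, what) {
  unknown <- setdiff(sym, rownames(.elem_tab))
  if (length(unknown))
    stop("element(s) outside the supported organic subset: ",
         paste(unique(unknown), collapse = ", "))
  .elem_tab[sym, what]
}

#' Parse SMILES into molecular graphs
#'
#' Converts SMILES to hydrogen-explicit connection tables via OpenBabel
#' (through ChemmineOB/ChemmineR) and extracts, per molecule, the
#' hydrogen-depleted heavy-atom graph with kekulized bond orders plus the
#' hydrogen count of each heavy atom. All 0D-2D descriptors are computed from
#' this graph; no conformers are ever generated.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids compound identifiers (default names of \code{smiles} or
#'   generated).
#' @return list of molecular graphs: each a list with \code{elem} (heavy-atom
#'   symbols), \code{A} (heavy-atom bond-order matrix), \code{nH} (hydrogens
#'   per heavy atom), and \code{sdf} (the hydrogen-explicit ChemmineR SDF,
#'   kept for property and SMARTS calculations).
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- names(smiles)
  if (is.null(ids)) ids <- sprintf("CPD%04d", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  bad <- which(is.na(smiles) | !nzchar(smiles) | grepl("\\.", smiles))
  if (length(bad))
    stop("invalid (missing or multi-fragment) SMILES for: ",
         paste(ids[bad], collapse = ", "))
  src <- paste(paste(smiles, ids), collapse = "\n")
  txt <- ChemmineOB::convertFormat("SMI", "SDF", src,
                                   options = data.frame(names = "h",
                                                        args = ""))
  sdfset <- suppressWarnings(
    methods::as(ChemmineR::read.SDFstr(strsplit(txt, "\n", fixed = TRUE)[[1]]),
                "SDFset"))
  if (length(sdfset) != length(smiles))
    stop("SMILES parsing failed: OpenBabel returned ", length(sdfset),
         " molecules for ", length(smiles), " inputs")
  ChemmineR::cid(sdfset) <- ids
  out <- lapply(seq_along(sdfset), function(i) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    sym <- sub("_.*$", "", rownames(ab))
    M <- ChemmineR::conMA(sdf)
    if (is.null(dim(M))) M <- matrix(0, length(sym), length(sym))
    heavy <- which(sym != "H")
    if (!length(heavy)) stop("molecule ", ids[i], " has no heavy atoms")
    A <- M[heavy, heavy, drop = FALSE]
    nH <- vapply(heavy, function(a) sum(sym[M[a, ] > 0] == "H"), 0L)
    conn <- (A > 0) + 0
    if (length(heavy) > 1) {
      g <- igraph::graph_from_adjacency_matrix(conn, mode = "undirected")
      if (igraph::components(g)$no > 1)
        stop("disconnected heavy-atom graph (multi-fragment input): ", ids[i])
    }
    list(id = ids[i], elem = sym[heavy], A = A, nH = nH)
  })
  names(out) <- ids
  attr(out, "sdfset") <- sdfset
  out
}

# topological distance matrix of the heavy-atom graph
.topo_dist <- function(A) {
  n <- nrow(A)
  if (n == 1) return(matrix(0, 1, 1))
  g <- igraph::graph_from_adjacency_matrix((A > 0) + 0, mode = "undirected")
  igraph::distances(g)
}

# per-molecule descriptor calculators; each returns a named numeric vector ----

.desc_constitutional <- function(mol) {
  el <- mol$elem; A <- mol$A; nH <- mol$nH
  n <- length(el)
  mass <- .elem_prop(el, "mass")
  bonds <- A[upper.tri(A)]
  nBO <- sum(bonds > 0)
  counts <- c(table(factor(el, levels = rownames(.elem_tab))), H = sum(nH))
  counts <- counts[counts > 0]
  nAT <- n + sum(nH)
  iac <- nAT * log2(nAT) - sum(counts * log2(counts))
  mw <- sum(mass) + sum(nH) * .elem_tab["H", "mass"]
  c(nAT = nAT, nSK = n, nBT = nBO + sum(nH), nBO = nBO,
    nC = sum(el == "C"), nN = sum(el == "N"), nO = sum(el == "O"),
    nX = sum(el %in% c("F", "Cl", "Br", "I")),
    nDB = sum(bonds == 2), nTB = sum(bonds == 3),
    nCyc = nBO - n + 1,
    MW = mw, AMW = mw / nAT, IAC = iac,
    Sv = (sum(.elem_prop(el, "v_vdw")) + sum(nH) * .elem_tab["H", "v_vdw"]) /
      .elem_tab["C", "v_vdw"],
    Se = (sum(.elem_prop(el, "en")) + sum(nH) * .elem_tab["H", "en"]) /
      .elem_tab["C", "en"])
}

.desc_topological <- function(mol) {
  A <- mol$A
  n <- nrow(A)
  if (n == 1)
    return(c(W = 0, Har = 0, ZM1 = 0, ZM2 = 0, Diam = 0, Rad = 0,
             PJI2 = 0, BalJ = 0))
  D <- .topo_dist(A)
  deg <- rowSums(A > 0)
  ecc <- apply(D, 1, max)
  diam <- max(ecc); rad <- min(ecc)
  edges <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  sig <- rowSums(D)
  m <- nrow(edges)
  mu <- m - n + 1                      # cyclomatic number
  balj <- if (m > 0) m / (mu + 1) *
    sum(1 / sqrt(sig[edges[, 1]] * sig[edges[, 2]])) else 0
  c(W = sum(D) / 2,
    Har = sum(1 / D[upper.tri(D) & D > 0]),
    ZM1 = sum(deg^2),
    ZM2 = sum(deg[edges[, 1]] * deg[edges[, 2]]),
    Diam = diam, Rad = rad,
    PJI2 = if (rad > 0) (diam - rad) / rad else 0,
    BalJ = balj)
}

# Kier-Hall simple and valence connectivity indices of order 0-2
.desc_connectivity <- function(mol) {
  A <- mol$A; el <- mol$elem; nH <- mol$nH
  n <- nrow(A)
  deg <- if (n > 1) rowSums(A > 0) else 0
  Z <- .elem_prop(el, "Z"); Zv <- .elem_prop(el, "Zv")
  dv <- (Zv - nH) / pmax(Z - Zv - 1, 1)
  chi <- function(d) {
    d0 <- d[d > 0]
    x0 <- sum(1 / sqrt(d0))
    edges <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
    x1 <- if (nrow(edges)) sum(1 / sqrt(d[edges[, 1]] * d[edges[, 2]])) else 0
    # paths of length 2: distinct neighbor pairs around each center atom
    x2 <- 0
    if (n > 2) {
      for (c0 in seq_len(n)) {
        nb <- which(A[c0, ] > 0)
        if (length(nb) >= 2) {
          pr <- utils::combn(nb, 2)
          x2 <- x2 + sum(1 / sqrt(d[pr[1, ]] * d[c0] * d[pr[2, ]]))
        }
      }
    }
    c(x0, x1, x2)
  }
  s <- chi(deg); v <- chi(pmax(dv, 1e-8))
  c(X0 = s[1], X1 = s[2], X2 = s[3],
    X0v = v[1], X1v = v[2], X2v = v[3],
    X0Av = s[1] / n, X1Av = if (n > 1) s[2] / max(sum(A > 0) / 2, 1) else 0)
}

# Moreau-Broto autocorrelations at topological lags 1-4, weighted by atomic
# mass, Sanderson electronegativity and van der Waals volume (carbon-scaled)
.desc_autocorrelation <- function(mol) {
  el <- mol$elem
  D <- .topo_dist(mol$A)
  w <- cbind(m = .elem_prop(el, "mass") / .elem_tab["C", "mass"],
             e = .elem_prop(el, "en") / .elem_tab["C", "en"],
             v = .elem_prop(el, "v_vdw") / .elem_tab["C", "v_vdw"])
  out <- numeric(0)
  for (p in colnames(w)) {
    for (k in 1:4) {
      idx <- which(D == k & upper.tri(D), arr.ind = TRUE)
      val <- if (nrow(idx)) sum(w[idx[, 1], p] * w[idx[, 2], p]) else 0
      out[sprintf("ATS%s%d", p, k)] <- val
    }
  }
  out
}

.desc_eigen <- function(mol) {
  A <- (mol$A > 0) + 0
  n <- nrow(A)
  ev <- if (n > 1) eigen(A, symmetric = TRUE, only.values = TRUE)$values else 0
  burden <- function(w) {
    B <- matrix(0.001, n, n)
    bonded <- mol$A > 0
    B[bonded] <- mol$A[bonded] / 10
    diag(B) <- w
    e <- sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
    hi <- c(e, 0, 0)[1:2]
    lo <- c(rev(e), 0, 0)[1:2]
    c(hi, lo)
  }
  bm <- burden(.elem_prop(mol$elem, "mass") / .elem_tab["C", "mass"])
  be <- burden(.elem_prop(mol$elem, "en") / .elem_tab["C", "en"])
  c(LP1 = max(ev), EigMin = min(ev), GraphE = sum(abs(ev)),
    BEHm1 = bm[1], BEHm2 = bm[2], BELm1 = bm[3], BELm2 = bm[4],
    BEHe1 = be[1], BEHe2 = be[2], BELe1 = be[3], BELe2 = be[4])
}

.desc_walkpath <- function(mol) {
  A <- (mol$A > 0) + 0
  out <- numeric(0)
  Ak <- A
  for (k in 2:5) {
    Ak <- Ak %*% A
    out[sprintf("MWC%d", k)] <- log1p(sum(Ak) / 2)
    out[sprintf("SRW%d", k)] <- log1p(sum(diag(Ak)))
  }
  out
}

# blocks computed set-wise from the hydrogen-explicit SDFs -------------------

.desc_properties_set <- function(sdfset) {
  p <- ChemmineR::propOB(sdfset)
  lip <- (p$MW > 500) + (p$logP > 5) + (p$HBD > 5) + (p$HBA2 > 10)
  m <- cbind(logP = p$logP, logP2 = p$logP^2, TPSA = p$TPSA, MR = p$MR,
             HBA = p$HBA2, HBD = p$HBD, RO5 = lip)
  rownames(m) <- ChemmineR::cid(sdfset)
  m
}

.desc_fgroups_set <- function(sdfset) {
  g <- ChemmineR::groups(sdfset, type = "countMA")
  if (is.null(dim(g))) g <- matrix(g, nrow = 1, dimnames = list(NULL, names(g)))
  hal <- t(vapply(ChemmineR::cid(sdfset), function(id) {
    ab <- ChemmineR::atomblock(sdfset[[id]])
    sym <- sub("_.*$", "", rownames(ab))
    c(nF = sum(sym == "F"), nCl = sum(sym == "Cl"),
      nBr = sum(sym == "Br"), nI = sum(sym == "I"))
  }, numeric(4)))
  rc <- tryCatch(ChemmineR::rings(sdfset, type = "count", arom = TRUE),
                 error = function(e) NULL)
  if (is.null(rc)) {
    rc <- matrix(0, length(sdfset), 2, dimnames = list(NULL, c("RINGS", "AROMATIC")))
  }
  m <- cbind(g, hal, nRing = rc[, "RINGS"], nArRing = rc[, "AROMATIC"])
  rownames(m) <- ChemmineR::cid(sdfset)
  m
}

#' Compute a block-organized 0D-2D descriptor matrix from SMILES
#'
#' Computes an open panel of conformation-independent descriptors organized
#' into 8 named blocks mirroring the families of the classical commercial
#' panels: \code{constitutional} (atom/bond/ring counts, molecular weight,
#' information index, atomic-property sums), \code{topological} (Wiener,
#' Harary, Zagreb, Balaban J, Petitjean shape), \code{connectivity}
#' (Kier-Hall simple and valence chi), \code{autocorrelation} (Moreau-Broto
#' lags 1-4 by mass, electronegativity, van der Waals volume),
#' \code{fgroups} (functional-group, halogen and ring counts),
#' \code{eigenvalue} (adjacency spectrum and Burden-matrix eigenvalues),
#' \code{properties} (logP, TPSA, molar refractivity, H-bond counts,
#' rule-of-five violations) and \code{walkpath} (log-scaled molecular walk
#' and self-returning walk counts). Everything is computed from the molecular
#' graph alone; no 3D descriptor appears. The result is deterministic for a
#' fixed input.
#'
#' @param compounds a compound table (see [read_compounds]) whose rows all
#'   carry a valid SMILES, or a character vector of SMILES.
#' @param blocks optional character vector naming which blocks to compute
#'   (default: all 8).
#' @return a [descriptor_matrix]; non-finite values (possible for degenerate
#'   graphs) are left as returned and can be handled with
#'   [impute_nonfinite].
#' @export
compute_descriptor_blocks <- function(compounds, blocks = NULL) {
  if (is.character(compounds))
    compounds <- data.frame(id = if (is.null(names(compounds)))
      sprintf("CPD%04d", seq_along(compounds)) else names(compounds),
      smiles = unname(compounds), stringsAsFactors = FALSE)
  mols <- parse_smiles(compounds$smiles, compounds$id)
  sdfset <- attr(mols, "sdfset")
  per_mol <- list(constitutional = .desc_constitutional,
                  topological = .desc_topological,
                  connectivity = .desc_connectivity,
                  autocorrelation = .desc_autocorrelation,
                  eigenvalue = .desc_eigen,
                  walkpath = .desc_walkpath)
  all_blocks <- c(names(per_mol), "fgroups", "properties")
  if (is.null(blocks)) blocks <- all_blocks
  stopifnot(all(blocks %in% all_blocks), length(blocks) >= 1)
  pieces <- list()
  for (b in intersect(names(per_mol), blocks)) {
    pieces[[b]] <- t(vapply(mols, per_mol[[b]],
                            per_mol[[b]](mols[[1]])))
  }
  if ("fgroups" %in% blocks) pieces$fgroups <- .desc_fgroups_set(sdfset)
  if ("properties" %in% blocks) pieces$properties <- .desc_properties_set(sdfset)
  pieces <- pieces[intersect(all_blocks, blocks)]
  values <- do.call(cbind, pieces)
  rownames(values) <- compounds$id
  manifest <- lapply(pieces, colnames)
  descriptor_matrix(values, manifest)
}

#' Names of the nine property descriptors used for partition refinement
#'
#' The k-means refinement of the structural clusters runs on nine normalized
#' global-property descriptors: molecular weight, logP, polar surface area,
#' H-bond acceptor and donor counts, total information index of atomic
#' composition, carbon-scaled sums of van der Waals volumes and Sanderson
#' electronegativities, and the 2D Petitjean shape index.
#'
#' @return character vector of nine descriptor names present in the output of
#'   [compute_descriptor_blocks].
#' @export
property_descriptor_names <- function() {
  c("MW", "logP", "TPSA", "HBA", "HBD", "IAC", "Sv", "Se", "PJI2")
}
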