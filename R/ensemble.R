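ELEMENT_SYMBOLS <- c(
  "H","He","Li","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P","S",
  "Cl","Ar","K","Ca","Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu","Zn","Ga",
  "Ge","As","Se","Br","Kr","Rb","Sr","Y","Zr","Nb","Mo","Tc","Ru","Rh","Pd",
  "Ag","Cd","In","Sn","Sb","Te","I","Xe","Cs","Ba","La","Ce","Pr","Nd","Pm",
  "Sm","Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb","Lu","Hf","Ta","W","Re","Os",
  "Ir","Pt","Au","Hg","Tl","Pb","Bi","Po","At","Rn","Fr","Ra","Ac","Th","Pa",
  "U","Np","Pu","Am","Cm","Bk","Cf","Es","Fm","Md","No","Lr","Rf","Db","Sg",
  "Bh","Hs","Mt","Ds","Rg","Cn","Nh","Fl","Mc","Lv","Ts","Og","D")

AVOGADRO <- 6.02214076e23

normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

#' A single conformer with designated label sites
#'
#' Atomic coordinates (nm) of one conformation plus the indices of the
#' spin-label attachment atoms around which local proton concentrations are
#' evaluated. Deuterium (`"D"`) is accepted as an element but never counted
#' as a proton.
#'
#' @param elements Character vector of element symbols.
#' @param xyz Numeric matrix, one row per atom, columns x/y/z in nm.
#' @param label_sites Integer indices into the atom list.
#' @return An object of class `conformer`.
#' @export
conformer <- function(elements, xyz, label_sites) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have three columns")
  n <- nrow(xyz)
  if (length(elements) != n) stop("one element symbol per atom required")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  elements <- normalize_element(elements)
  bad <- setdiff(unique(elements), ELEMENT_SYMBOLS)
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  label_sites <- as.integer(label_sites)
  if (length(label_sites) < 1L || any(label_sites < 1L) || any(label_sites > n)) {
    stop("label_sites must be valid atom indices")
  }
  structure(list(elements = elements, xyz = xyz, label_sites = label_sites),
            class = "conformer")
}

is_conformer <- function(x) inherits(x, "conformer")

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("conformer: %d atoms (%d H), %d label site(s)\n",
              nrow(x$xyz), sum(x$elements == "H"), length(x$label_sites)))
  invisible(x)
}

# hydrogens whose nearest heavy atom within 0.13 nm is O or N (labile in a
# deuterated matrix)
exchangeable_mask <- function(conf, bond_cut = 0.13) {
  is_h <- conf$elements == "H"
  out <- logical(length(conf$elements))
  heavy <- which(!is_h & conf$elements != "D")
  if (!length(heavy) || !any(is_h)) return(out)
  hxyz <- conf$xyz[is_h, , drop = FALSE]
  for (i in seq_len(nrow(hxyz))) {
    d2 <- rowSums((conf$xyz[heavy, , drop = FALSE] -
                   matrix(hxyz[i, ], length(heavy), 3, byrow = TRUE))^2)
    j <- which.min(d2)
    if (d2[j] <= bond_cut^2 && conf$elements[heavy[j]] %in% c("O", "N")) {
      out[which(is_h)[i]] <- TRUE
    }
  }
  out
}

#' Local proton concentration around a label site
#'
#' Counts hydrogen atoms within a sphere of `radius` (default 2.5 nm) around
#' the designated site atom and converts the count to a molar concentration,
#' C_H = N_H / (N_A · V) with V = (4/3)π(radius³ − inner_radius³) in liters.
#' Exchangeable hydrogens (O–H/N–H, labile and hence deuterated in a
#' D₂O/d₆-DMSO matrix) are excluded by default.
#'
#' @param conf A [conformer()].
#' @param site Atom index of the label site (need not be listed in
#'   `label_sites`).
#' @param radius Sphere radius, nm. Default 2.5.
#' @param include_exchangeable Count O–H/N–H hydrogens too. Default `FALSE`.
#' @param inner_radius Optional excluded core radius, nm. Default 0.
#' @return Concentration, mol/L.
#' @examples
#' # 394 protons uniformly inside 2.5 nm correspond to ~10 mol/L
#' @export
local_proton_concentration <- function(conf, site, radius = 2.5,
                                       include_exchangeable = FALSE,
                                       inner_radius = 0) {
  stopifnot(is_conformer(conf))
  site <- as.integer(site)
  if (length(site) != 1L || site < 1L || site > nrow(conf$xyz)) {
    stop("site index out of range")
  }
  if (radius <= 0 || inner_radius < 0 || inner_radius >= radius) {
    stop("need 0 <= inner_radius < radius")
  }
  center <- conf$xyz[site, ]
  d2 <- rowSums((conf$xyz - matrix(center, nrow(conf$xyz), 3, byrow = TRUE))^2)
  sel <- conf$elements == "H" & d2 <= radius^2 & d2 >= inner_radius^2
  if (!include_exchangeable && any(sel)) {
    sel <- sel & !exchangeable_mask(conf)
  }
  vol_liters <- (4 / 3) * pi * (radius^3 - inner_radius^3) * 1e-24  # nm^3 -> L
  sum(sel) / (AVOGADRO * vol_liters)
}

#' Histogram of local proton concentrations over a conformer ensemble
#'
#' Pools [local_proton_concentration()] over every (conformer, label site)
#' pair and bins the values on the concentration grid, yielding the
#' ensemble-predicted p(C_H) against which the trace-derived distribution
#' can be cross-checked. Values outside the grid are counted into the
#' nearest end bin.
#'
#' @param ensemble List of [conformer()] objects, each with ≥ 1 label site.
#' @param radius Sphere radius, nm. Default 2.5.
#' @param c_grid Concentration grid, mol/L.
#' @param include_exchangeable Passed to [local_proton_concentration()].
#' @param inner_radius Passed to [local_proton_concentration()].
#' @return A [density_distribution] with attribute `values` holding the
#'   pooled concentrations.
#' @export
ensemble_histogram <- function(ensemble, radius = 2.5,
                               c_grid = default_c_grid(),
                               include_exchangeable = FALSE,
                               inner_radius = 0) {
  if (!is.list(ensemble) || length(ensemble) < 1L ||
      !all(vapply(ensemble, is_conformer, logical(1)))) {
    stop("ensemble must be a non-empty list of conformers")
  }
  values <- unlist(lapply(ensemble, function(conf) {
    vapply(conf$label_sites, function(s) {
      local_proton_concentration(conf, s, radius,
                                 include_exchangeable, inner_radius)
    }, numeric(1))
  }), use.names = FALSE)
  dc <- mean(diff(c_grid))
  bin <- pmin(pmax(round((values - c_grid[1]) / dc) + 1L, 1L), length(c_grid))
  counts <- tabulate(bin, nbins = length(c_grid))
  out <- density_distribution(c_grid, counts / (length(values) * dc))
  attr(out, "values") <- values
  out
}

#' Read a conformer ensemble from a multi-model PDB file
#'
#' Each `MODEL` record becomes one conformer; coordinates are converted from
#' Å to nm. Requires the `bio3d` package. Structures without explicit
#' hydrogens are rejected rather than guessing positions.
#'
#' @param path PDB file path.
#' @param label_serials Atom serial numbers (PDB `eleno`) of the label sites.
#' @return List of [conformer()] objects.
#' @export
read_conformers_pdb <- function(path, label_serials) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("package 'bio3d' is required to read PDB files")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  elements <- pdb$atom$elesy
  if (is.null(elements) || all(is.na(elements)) || all(elements == "")) {
    elements <- substr(trimws(pdb$atom$elety), 1, 1)
  }
  elements <- normalize_element(elements)
  if (!any(elements == "H")) {
    stop("structure has no explicit hydrogens; cannot count protons")
  }
  sites <- match(as.integer(label_serials), pdb$atom$eleno)
  if (any(is.na(sites))) {
    stop("label serial(s) not found: ",
         paste(label_serials[is.na(sites)], collapse = ", "))
  }
  frames <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  xyz_mat <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1L)
  lapply(seq_len(frames), function(f) {
    xyz <- matrix(xyz_mat[f, ], ncol = 3L, byrow = TRUE) / 10  # A -> nm
    conformer(elements, xyz, sites)
  })
}

#' Read a conformer ensemble from a frame-concatenated XYZ file
#'
#' Standard XYZ layout: an atom-count line, a comment line, then
#' `element x y z` per atom; frames concatenated. Coordinates are converted
#' from Å to nm unless `unit = "nm"`.
#'
#' @param path XYZ file path.
#' @param label_sites Atom indices (within each frame) of the label sites.
#' @param unit `"angstrom"` (default) or `"nm"`.
#' @return List of [conformer()] objects.
#' @export
read_conformers_xyz <- function(path, label_sites, unit = c("angstrom", "nm")) {
  unit <- match.arg(unit)
  lines <- readLines(path)
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("malformed XYZ atom count at line ", i)
    if (i + 1L + n > length(lines)) stop("truncated XYZ frame at line ", i)
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    el <- vapply(rows, `[[`, character(1), 1L)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) stop("non-numeric coordinates in XYZ frame at line ", i)
    if (unit == "angstrom") xyz <- xyz / 10
    out[[length(out) + 1L]] <- conformer(el, xyz, label_sites)
    i <- i + 2L + n
  }
  if (!length(out)) stop("no frames found in ", path)
  out
}
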