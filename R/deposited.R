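#' Recompute the deposited-data reference quantities
#'
#' Reproduces, from user-supplied deposited files, the published reference
#' numbers of the crosslink-validation and interface-area analyses:
#' the number of crosslinks mappable at ld >= 40 and the number violating the
#' 35 A cutoff on the tau-A + Brf1-TBP coordinates, and the areas buried by
#' the tau-95 acidic plug (residues 566-592) and the tau-131 C-terminal TPR
#' against the tau-95 DNA-binding domain (residues 263-509).
#'
#' The inputs are deposited third-party data and must be downloaded by the
#' user; they are not shipped with the package. \code{dir} must contain:
#' \describe{
#'   \item{\code{tauA.pdb} (or \code{.cif})}{the deposited tau-A coordinates
#'     (PDB accession 6YJ6).}
#'   \item{\code{brf1_tbp.pdb} (or \code{.cif})}{Brf1-TBP coordinates chosen
#'     by the user (no specific accession is prescribed).}
#'   \item{\code{crosslinks.tsv}}{the exported 5 percent-FDR crosslink table
#'     (xQuest-style columns).}
#'   \item{\code{chain_map.yaml}}{protein-name to chain-id mapping for the two
#'     structures (never guessed).}
#' }
#'
#' @param dir directory containing the deposited files.
#' @param plug_sel,dbd_sel,tpr_sel selection strings for the acidic plug, the
#'   DNA-binding domain and the C-terminal TPR. Two TPR spans are plausible
#'   readings (733-1025 or 612-1025); both are supported via \code{tpr_sel}.
#' @return List with \code{n_mapped}, \code{n_violated},
#'   \code{buried_plug_dbd}, \code{buried_tpr_dbd} (angstrom^2).
#' @export
reproduce_deposited_targets <- function(dir,
                                        plug_sel = "C:566-592",
                                        dbd_sel = "C:263-509",
                                        tpr_sel = "A:733-1025") {
  find1 <- function(base) {
    for (ext in c("pdb", "cif")) {
      p <- file.path(dir, paste0(base, ".", ext))
      if (file.exists(p)) return(p)
    }
    stop("deposited input not found: ", file.path(dir, paste0(base, ".pdb")),
         " (download required; see ?reproduce_deposited_targets)")
  }
  tauA <- read_structure(find1("tauA"))
  brf1 <- read_structure(find1("brf1_tbp"))
  xl_path <- file.path(dir, "crosslinks.tsv")
  cm_path <- file.path(dir, "chain_map.yaml")
  if (!file.exists(xl_path) || !file.exists(cm_path))
    stop("deposited crosslink table or chain map not found in ", dir)
  links <- read_xlink_table(xl_path)
  chain_map <- yaml::read_yaml(cm_path)
  cfg <- xlink_config(ld_min = 40, max_distance = 35, chain_map = chain_map)
  brf1_atoms <- brf1$atoms
  # avoid chain-id collisions between the two structures
  shared <- intersect(unique(tauA$atoms$chain), unique(brf1_atoms$chain))
  if (length(shared))
    warning("chain ids shared between structures: ",
            paste(shared, collapse = ", "),
            "; the chain map must disambiguate them")
  assembly <- atomic_model(rbind(tauA$atoms, brf1_atoms))
  mapping <- map_crosslinks(assembly, links, cfg)
  list(n_mapped = mapping$totals$n_mapped,
       n_violated = mapping$totals$n_violated,
       buried_plug_dbd = buried_area(tauA, plug_sel, dbd_sel),
       buried_tpr_dbd = buried_area(tauA, tpr_sel, dbd_sel),
       mapping = mapping)
}

#' Default location for deposited reference inputs
#'
#' Deposited files are looked for under \code{inst/deposited} of the
#' installed package first and then under \code{~/.local/share/stainfit}.
#' @return The first existing directory, or the user path if none exists.
#' @export
deposited_data_dir <- function() {
  cand <- c(system.file("deposited", package = "stainfit"),
            file.path(path.expand("~"), ".local", "share", "stainfit"))
  cand <- cand[nzchar(cand)]
  for (p in cand) if (dir.exists(p)) return(p)
  cand[length(cand)]
}
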