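# SMARTS patterns for the 16 functional groups, with exclusive priority on
# carbonyl carbons: acid > ester > amide > aldehyde > ketone.
# - acid requires the protic oxygen, ester the alkylated one, so they are
#   mutually exclusive; the amide pattern excludes carbonyls bearing an
#   ether oxygen so carbamates count as esters only;
# - aldehyde/ketone require carbon neighbours, excluding all of the above;
# - phenolic vs alcoholic OH split on aromatic vs sp3 carbon;
# - the amine pattern excludes amide nitrogens;
# - the ether oxygen excludes carbonyl-bonded oxygens (ester linkages);
# - methyl is a CH3 with exactly one heavy-atom neighbour (so e.g. the
#   acetyl CH3 of ethyl acetate still counts);
# - halogens are counted as atoms.
fg_smarts <- function() {
  c(CtPh    = "[OX2H1][c]",
    CtOH    = "[OX2H1][CX4]",
    CtAl    = "[CX3H1](=[OX1])[#6]",
    CtCO2H  = "[CX3](=[OX1])[OX2H1]",
    CtRCO2R = "[CX3](=[OX1])[OX2H0][#6]",
    CtR2CO  = "[#6][CX3](=[OX1])[#6]",
    CtROR   = "[OX2H0]([#6;!$([CX3]=[OX1])])[#6;!$([CX3]=[OX1])]",
    CtCN    = "[CX2]#[NX1]",
    CtNH2   = "[NX3;H2;!$([NX3][CX3]=[OX1])]",
    CtNO2   = "[$([NX3](=O)=O),$([NX3+](=O)[O-])]",
    CtAm    = "[NX3][CX3;!$([CX3][OX2])](=[OX1])",
    CtMe    = "[CX4H3;D1]",
    CtF     = "[#9]",
    CtCl    = "[#17]",
    CtBr    = "[#35]",
    CtI     = "[#53]")
}

require_chemminer <- function() {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("SMILES featurization needs the ChemmineR and ChemmineOB packages")
  }
}

parse_smiles <- function(smiles) {
  require_chemminer()
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (is.null(names(smiles))) {
    names(smiles) <- sprintf("m%d", seq_along(smiles))
  }
  # parse one at a time so a bad structure can be named
  sdfs <- lapply(seq_along(smiles), function(i) {
    tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles[i])),
             error = function(e) {
               stop(sprintf("cannot parse SMILES '%s' (input %d)",
                            smiles[[i]], i), call. = FALSE)
             })
  })
  out <- sdfs[[1]]
  if (length(sdfs) > 1) for (i in 2:length(sdfs)) out <- c(out, sdfs[[i]])
  ChemmineR::cid(out) <- names(smiles)
  out
}

#' Count the 16 representative functional groups in a molecule
#'
#' Counts substructure matches of the documented SMARTS patterns, with
#' exclusive priority rules on carbonyl carbons (carboxylic acid > ester >
#' amide > aldehyde > ketone) so that each carbonyl contributes to exactly
#' one count.  Deterministic and invariant to SMILES atom ordering.
#'
#' @param smiles character vector of SMILES strings (optionally named).
#' @return for a single structure, a named integer vector of length 16; for
#'   several, an integer matrix with one row per structure.
#' @examples
#' \dontrun{
#' count_functional_groups("Oc1ccccc1")  # phenol: CtPh = 1
#' }
#' @export
count_functional_groups <- function(smiles) {
  sdf <- parse_smiles(smiles)
  pats <- fg_smarts()
  counts <- vapply(pats, function(p) {
    as.integer(ChemmineR::smartsSearchOB(sdf, p, uniqueMatches = TRUE))
  }, integer(length(smiles)))
  if (length(smiles) == 1L) {
    return(stats::setNames(as.integer(counts), names(pats)))
  }
  rownames(counts) <- names(smiles)
  counts
}

#' Count six-membered carbocyclic aromatic rings
#'
#' Benzene rings only: fused systems contribute one count per six-membered
#' all-carbon aromatic ring (naphthalene counts 2), heteroaromatic rings do
#' not count.
#'
#' @param smiles character vector of SMILES strings.
#' @return integer vector.
#' @examples
#' \dontrun{
#' count_benzene_rings(c("c1ccccc1", "CCCCCC"))  # 1, 0
#' }
#' @export
count_benzene_rings <- function(smiles) {
  sdf <- parse_smiles(smiles)
  as.integer(ChemmineR::smartsSearchOB(sdf, "c1ccccc1", uniqueMatches = TRUE))
}

#' Featurize molecules given as SMILES into a TLC dataset
#'
#' Builds the canonical dataset table from structures, dipole moments and
#' solvent compositions.  The dipole moment is consumed as a provided
#' numeric column, never computed.
#'
#' @param smiles character vector of SMILES.
#' @param dm dipole moments (Debye), recycled if scalar.
#' @param solvent data.frame/matrix with the five solvent columns (one row
#'   per sample, or a single row recycled).
#' @param rf observed Rf values, or `NA`.
#' @param id record labels.
#' @return data.frame of class `tlc_dataset`.
#' @export
featurize_smiles <- function(smiles, dm, solvent, rf = NA_real_, id = NULL) {
  fg <- count_functional_groups(smiles)
  if (is.null(dim(fg))) fg <- matrix(fg, nrow = 1, dimnames = list(NULL, names(fg)))
  nb <- count_benzene_rings(smiles)
  solvent <- as.data.frame(solvent)
  if (nrow(solvent) == 1L && length(smiles) > 1L) {
    solvent <- solvent[rep(1L, length(smiles)), , drop = FALSE]
  }
  if (is.null(id)) id <- names(smiles)
  tlc_dataset(solvent, fg, n_ben = nb, dm = rep_len(dm, length(smiles)),
              rf = rf, id = id)
}
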