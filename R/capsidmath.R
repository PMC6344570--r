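# Icosahedral capsid bookkeeping: copy-number census (everything scales
# by the 60 icosahedral asymmetric units), Caspar-Klug triangulation
# arithmetic, symmetron capsomer counts, tape-measure length scaling, and
# N-glycosylation sequon scanning.

#' Build a per-asymmetric-unit copy-number table
#'
#' @param protein_id Character vector of unique protein ids.
#' @param copies_per_au Positive integer copies of each protein per
#'   icosahedral asymmetric unit.
#' @param category Optional grouping (e.g. `"major"`, `"penton"`,
#'   `"minor"`) used for category subtotals.
#' @return A `census_table` data.frame.
#' @export
census_table <- function(protein_id, copies_per_au, category = NA_character_) {
  if (anyDuplicated(protein_id)) stop("protein ids must be unique", call. = FALSE)
  copies_per_au <- as.integer(copies_per_au)
  if (anyNA(copies_per_au) || any(copies_per_au < 1L)) {
    stop("copies_per_au must be positive integers", call. = FALSE)
  }
  category <- rep_len(as.character(category), length(protein_id))
  structure(data.frame(protein_id = as.character(protein_id),
                       copies_per_au = copies_per_au,
                       category = category,
                       stringsAsFactors = FALSE),
            class = c("census_table", "data.frame"))
}

#' The PBCV-1 capsid census
#'
#' Chains per icosahedral asymmetric unit (AU) of the PBCV-1 capsid: the
#' major capsid protein Vp54 contributes 28 pseudo-hexameric capsomers
#' per AU at 3 chains each (84 chains/AU), the penton protein 1 chain/AU,
#' and the 13 minor capsid proteins 1 chain/AU each except P3 (3),
#' P4 (4), P10 (2) and the zip protein P11 (12).
#'
#' @param capsomers_per_au Pseudo-hexameric capsomers per AU; default 28.
#' @param chains_per_capsomer MCP chains per pseudo-hexamer; default 3.
#' @return A `census_table`.
#' @export
pbcv1_census <- function(capsomers_per_au = 28L, chains_per_capsomer = 3L) {
  minors <- c(P2 = 1L, P3 = 3L, P4 = 4L, P5 = 1L, P6 = 1L, P7 = 1L, P8 = 1L,
              P9 = 1L, P10 = 2L, P11 = 12L, P12 = 1L, P13 = 1L, P14 = 1L)
  census_table(
    protein_id = c("Vp54", "penton", names(minors)),
    copies_per_au = c(capsomers_per_au * chains_per_capsomer, 1L,
                      unname(minors)),
    category = c("major", "penton", rep("minor", length(minors)))
  )
}

#' Whole-virion copy totals from a per-AU census
#'
#' Multiplies each per-AU copy number by the 60 icosahedral asymmetric
#' units and reports per-protein totals, per-category subtotals and the
#' grand total of polypeptide chains.
#'
#' @param table A `census_table` (may have zero rows).
#' @param n_au Asymmetric units per icosahedron; 60 by construction.
#' @return List with `per_protein` (data.frame adding `copies_virion`),
#'   `by_category` (named totals) and `total_chains`.
#' @export
#' @examples
#' capsid_census(pbcv1_census())$by_category  # major 5040, penton 60, minor 1800
capsid_census <- function(table, n_au = 60L) {
  per <- as.data.frame(table)
  per$copies_virion <- if (nrow(per)) per$copies_per_au * as.integer(n_au) else integer(0)
  by_cat <- if (nrow(per)) {
    tapply(per$copies_virion, per$category, sum)
  } else {
    stats::setNames(integer(0), character(0))
  }
  list(per_protein = per,
       by_category = by_cat,
       total_chains = sum(per$copies_virion))
}

#' Triangulation number from chain stoichiometry
#'
#' Each pseudo-hexameric capsomer position on a T-lattice carries 6
#' jelly-roll domains and each icosahedron has 60 T jelly rolls in total;
#' with the MCP contributing `rolls_per_mcp` jelly-roll domains per chain
#' (2 for a double jelly-roll MCP) and the penton protein
#' `rolls_per_penton` (1), the lattice satisfies
#' `60 T = rolls_per_mcp * n_mcp_chains + rolls_per_penton * n_penton_chains`.
#'
#' @param n_mcp_chains Number of MCP chains in the virion.
#' @param n_penton_chains Number of penton chains in the virion.
#' @param rolls_per_mcp Jelly-roll domains per MCP chain; default 2.
#' @param rolls_per_penton Jelly-roll domains per penton chain; default 1.
#' @return Integer T.
#' @export
#' @examples
#' t_number_from_chains(5040, 60)  # 169
t_number_from_chains <- function(n_mcp_chains, n_penton_chains,
                                 rolls_per_mcp = 2L, rolls_per_penton = 1L) {
  total <- rolls_per_mcp * n_mcp_chains + rolls_per_penton * n_penton_chains
  if (total %% 60 != 0) {
    stop("inconsistent lattice: ", total,
         " jelly-roll domains is not divisible by 60", call. = FALSE)
  }
  as.integer(total / 60)
}

#' Caspar-Klug (h, k) lattice vectors for a given T number
#'
#' Exhaustively enumerates all non-negative integer pairs with
#' `h^2 + h*k + k^2 = T` and `h >= k`. Pairs with `h != k` and `k > 0`
#' describe a skew (chiral) lattice existing in laevo and dextro forms.
#'
#' @param T Triangulation number (>= 1).
#' @return data.frame with columns `h`, `k`, `chiral`; zero rows when no
#'   representation exists.
#' @export
#' @examples
#' hk_candidates(169)  # (13, 0) and the chiral pair (8, 7)
hk_candidates <- function(T) {
  T <- as.integer(T)
  if (is.na(T) || T < 1L) stop("T must be a positive integer", call. = FALSE)
  hmax <- as.integer(ceiling(sqrt(T)))
  out <- list()
  for (h in 0:hmax) {
    for (k in 0:h) {
      if (h * h + h * k + k * k == T) {
        out[[length(out) + 1L]] <- data.frame(h = h, k = k,
                                              chiral = (h != k && k > 0L))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(h = integer(0), k = integer(0), chiral = logical(0)))
  }
  do.call(rbind, out)
}

#' Capsomers in a triangular array with a given edge length
#'
#' @param edge Capsomers per edge (>= 1).
#' @return `edge * (edge + 1) / 2`.
#' @export
#' @examples
#' triangular_count(8)   # 36, the P3-linked array
#' triangular_count(11)  # 66, a full trisymmetron
triangular_count <- function(edge) {
  edge <- as.integer(edge)
  if (any(is.na(edge)) || any(edge < 1L)) stop("edge must be >= 1", call. = FALSE)
  (edge * (edge + 1L)) %/% 2L
}

#' Symmetron specification and capsomer counts
#'
#' A trisymmetron spans 3 asymmetric units, a pentasymmetron 5, so with
#' 22 trisymmetron and 6 pentasymmetron pseudo-hexamers per AU plus one
#' pentamer per pentasymmetron the counts are 3 x 22 = 66 and
#' 5 x 6 + 1 = 31.
#'
#' @param capsomers_per_au_tri Trisymmetron pseudo-hexamers per AU;
#'   default 22.
#' @param capsomers_per_au_penta Pentasymmetron pseudo-hexamers per AU;
#'   default 6.
#' @param pentamer_per_pentasymmetron Pentameric capsomers per
#'   pentasymmetron; default 1.
#' @return For `symmetron_spec`, a list; for
#'   `symmetron_capsomer_count`, a list with `per_trisymmetron` and
#'   `per_pentasymmetron`.
#' @export
symmetron_spec <- function(capsomers_per_au_tri = 22L,
                           capsomers_per_au_penta = 6L,
                           pentamer_per_pentasymmetron = 1L) {
  vals <- c(capsomers_per_au_tri, capsomers_per_au_penta,
            pentamer_per_pentasymmetron)
  if (any(vals < 0L)) stop("symmetron counts must be non-negative", call. = FALSE)
  structure(list(capsomers_per_au_tri = as.integer(capsomers_per_au_tri),
                 capsomers_per_au_penta = as.integer(capsomers_per_au_penta),
                 pentamer_per_pentasymmetron = as.integer(pentamer_per_pentasymmetron)),
            class = "symmetron_spec")
}

#' @rdname symmetron_spec
#' @param spec A `symmetron_spec`.
#' @export
#' @examples
#' symmetron_capsomer_count(symmetron_spec())  # 66 and 31
symmetron_capsomer_count <- function(spec = symmetron_spec()) {
  list(per_trisymmetron = 3L * spec$capsomers_per_au_tri,
       per_pentasymmetron = 5L * spec$capsomers_per_au_penta +
         spec$pentamer_per_pentasymmetron)
}

#' Tape-measure model and capsid-size scaling
#'
#' The tape-measure protein runs along a symmetron edge, so the number of
#' residues in its extended, shell-contacting span scales linearly with
#' capsid diameter. The reference is the PBCV-1 tape-measure protein P2:
#' 473 residues (94--566) against a ~190 nm capsid.
#'
#' @param ref_span_aa Residues in the reference shell-contacting span;
#'   default 473.
#' @param ref_diameter_nm Reference capsid diameter in nm; default 190.
#' @return A `tape_measure_model` list (also carries the jelly-roll
#'   constants used by [t_number_from_chains()]).
#' @export
tape_measure_model <- function(ref_span_aa = 473L, ref_diameter_nm = 190) {
  if (ref_span_aa <= 0 || ref_diameter_nm <= 0) {
    stop("reference span and diameter must be positive", call. = FALSE)
  }
  structure(list(ref_span_aa = as.integer(ref_span_aa),
                 ref_diameter_nm = as.numeric(ref_diameter_nm),
                 rolls_per_mcp_chain = 2L, rolls_per_penton_chain = 1L),
            class = "tape_measure_model")
}

#' @rdname tape_measure_model
#' @param target_diameter_nm Capsid diameter to scale to, in nm.
#' @param model A `tape_measure_model`.
#' @param rounding `"none"` for the raw linear estimate, or an integer k
#'   to round to the nearest k (default 50, the reporting granularity for
#'   "approximately" sized homologs).
#' @return For `tape_measure_estimate`, a list with `estimate` (raw) and
#'   `rounded` (`NA` when `rounding = "none"`).
#' @export
#' @examples
#' tape_measure_estimate(500)$rounded  # 1250 (APMV-sized capsid)
#' tape_measure_estimate(300)$rounded  # 750 (CroV-sized capsid)
tape_measure_estimate <- function(target_diameter_nm,
                                  model = tape_measure_model(),
                                  rounding = 50L) {
  if (any(target_diameter_nm <= 0)) stop("diameter must be positive", call. = FALSE)
  est <- model$ref_span_aa * target_diameter_nm / model$ref_diameter_nm
  rounded <- if (identical(rounding, "none")) NA_real_ else {
    k <- as.numeric(rounding)
    if (is.na(k) || k <= 0) stop("rounding must be 'none' or a positive integer", call. = FALSE)
    round(est / k) * k
  }
  list(estimate = est, rounded = rounded)
}

#' Length of a 1-based inclusive residue range
#'
#' @param start,end Residue numbers, 1-based inclusive, `end >= start`.
#' @return `end - start + 1`.
#' @export
#' @examples
#' residue_range_length(94, 566)  # 473
residue_range_length <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(end < start)) stop("end must be >= start", call. = FALSE)
  end - start + 1L
}

#' Scan a protein sequence for N-glycosylation sites
#'
#' Reports every asparagine with: whether it sits in the canonical
#' N-X-(T/S) sequon (threonine or serine two residues downstream; X
#' unrestricted), and whether it is preceded by a small residue (Ala or
#' Gly) — the feature shared by the glycosylated sites of the PBCV-1
#' penton protein and MCP even where the canonical sequon is absent.
#'
#' @param seq Amino-acid string.
#' @param canonical_only If `TRUE`, keep only canonical sequons.
#' @return data.frame with `position` (1-based position of N), `context`
#'   (5-residue window N-1..N+3, `-`-padded at the termini), `canonical`
#'   and `small_preceded`.
#' @export
#' @examples
#' sequon_scan("ANTTP")  # canonical, small-preceded
sequon_scan <- function(seq, canonical_only = FALSE) {
  seq <- toupper(as.character(seq))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(AA_STANDARD, AA_WILDCARD))
  if (length(bad)) {
    stop("illegal amino-acid code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  pos <- which(chars == "N")
  at <- function(i) ifelse(i >= 1L & i <= length(chars), chars[pmax(i, 1L)], "-")
  out <- data.frame(
    position = pos,
    context = vapply(pos, function(p) {
      paste(at(p + (-1:3)), collapse = "")
    }, ""),
    canonical = at(pos + 2L) %in% c("T", "S"),
    small_preceded = at(pos - 1L) %in% c("A", "G"),
    stringsAsFactors = FALSE
  )
  if (canonical_only) out <- out[out$canonical, , drop = FALSE]
  rownames(out) <- NULL
  out
}
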