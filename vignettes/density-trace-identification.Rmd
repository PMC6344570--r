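---
title: "Identifying proteins from side-chain-size traces in cryo-EM maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying proteins from side-chain-size traces in cryo-EM maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryotrace)
```

## The problem

At ~3.5 Å resolution, a cryo-EM map of a large icosahedral virus shows
main-chain connectivity and, where the density is good, the approximate
bulk of each side chain — but not its identity. A builder can therefore
trace a polypeptide through the map and record, per position, roughly how
large the side chain looks, without knowing which of the candidate virion
proteins the chain is. `cryotrace` turns that visual record into a
quantitative identification: both the map observations and every
candidate sequence are reduced to integer *size classes* 0–6, and the
trace is searched against each candidate under explicit scoring and
exclusion rules.

## The trace model

A **density trace** is an ordered list of segments, each a run of
elements of three kinds, mirroring the three poor-density situations a
builder encounters:

* **observed** — good side-chain density, summarized as a class 0–6;
* **ambiguous** — a reliable Cα but unreadable side chain: the residue
  could be any of the 20 possibilities. It occupies one candidate
  position but carries no evidence;
* **gap region** — main-chain connectivity without reliable Cα
  placement. The builder tentatively counts `n` residues with maximum
  error `x`; the region then holds between `ceil(n − x/2)` and `n + x`
  residues. With odd `x` the lower bound rounds toward the *wider*
  interval, so no admissible length is ever excluded.

Where density is completely missing the trace simply breaks into a new
segment; nothing is asserted about the missing stretch except that it has
non-negative length, so a multi-segment trace has an unbounded maximum
length. Traces serialize to a small JSON dialect (`parse_traces()` /
`write_traces()`); coordinates are 0-based within a segment.

## Scoring and the alignment search

Each aligned (observed, candidate) pair is scored from a 7×7 table on a
fixed [0, 1] scale: 1 for an exact class match, 0.5 for a one-class
mismatch in either direction, 0.25 when the candidate exceeds the
observation by two or more (flexible side chains are often partially
disordered, so density under-represents them). The rule is deliberately
one-sided: when the *observed* class exceeds the candidate's by 2 or more
the pair is not scored at all — the alignment is inadmissible, because a
map cannot show more side chain than the sequence provides. That
exclusion is structural and survives any table override. The default
class map (G=0 … R/F/Y/W=6, binned by side-chain heavy-atom count) and
score table are stand-in calibrations chosen to be monotone in physical
bulk; `load_config()` accepts a replacement table verbatim, so a
map-derived calibration can be dropped in without code changes.

`align_trace()` finds the admissible placement maximizing the *mean*
per-residue score by exact enumeration over window offsets, per-gap
lengths within their bounds, and left-to-right non-overlapping segment
placements. The trace may sit anywhere inside the candidate: both termini
may be unmodeled (extended minor capsid proteins are commonly ordered
only from an interior residue onward). Ambiguous trace positions and
wildcard candidate letters (X/B/Z/U) consume a position but are excluded
from both the numerator and the denominator of the mean — averaging over
uninformative positions would dilute real evidence. No insertions or
deletions are permitted inside observed runs; only gap regions and
missing regions absorb length uncertainty, which is exactly where the map
itself is uncertain.

Ties in mean score break deterministically (smallest start offset, then
lexicographically smallest gap-length tuple, then smallest later-segment
offsets); determinism matters because reports must be reproducible
byte-for-byte. Equality of the search with an independent brute-force
reference (`align_trace_oracle()`) is asserted over a thousand randomized
small instances in the test suite. The enumeration cost is the product of
the per-segment offset and gap ranges; a configurable placement budget
(default 5×10⁶) warns when an instance is unusually large. At the scale
this method targets — traces of tens to hundreds of residues with a
handful of gaps against proteomes of a few hundred sequences — exactness
is affordable and preferable to a heuristic.

## Screening, combining copies, deciding

`screen_proteome()` aligns one trace against every candidate (exclusions
recorded with reasons: `candidate_too_short`, `size_violation`,
`no_scored_positions`) and ranks candidates by best mean score.
`decide_assignment()` applies the final rule: a candidate is **assigned**
either when it is the *only* sequence with an admissible alignment, or
when its best score beats every other candidate's by more than the margin
(default 0.1 — meaningful precisely because scores live on a fixed [0, 1]
scale). Otherwise the decision is **ambiguous**, listing every candidate
within the margin of the top (the most informative superset of the
pairwise rule), or **no_match** when nothing aligns. When an assignment
wins by margin over other admissible candidates the result carries
`needs_ss_check = TRUE`: in the original workflow such runner-ups were
additionally rejected by secondary-structure prediction, an external tool
this package deliberately does not reimplement.

When several traced chains are believed to be copies of the same
polypeptide (e.g. the 12 short copies of a zip protein in one asymmetric
unit), `combine_copies()` pools their evidence — but only when each
copy's best match names the same candidate; otherwise it refuses
(`best_match_disagrees`). Structural similarity of the copies is
operationalized as identical trace skeletons (same segment structure and
positional element layout; observed vs ambiguous may differ per copy)
plus the caller's `group_id` — no superposition is computed, since the
package never sees coordinates. Per position, an observed class beats an
ambiguous one; two conflicting observed classes combine to the maximum,
on the reasoning that the larger class reflects the more complete
density, with the conflict logged rather than refused (the source
procedure defines no conflict rule, and refusing would discard usable
evidence). Gap regions combine by intersecting their bounds; an empty
intersection refuses (`gap_bounds_disjoint`), since the copies then
cannot be the same chain.

## The synthetic generator

`generate_proteome()` and `simulate_trace()` provide ground-truth
benchmarks without any external data. Decoy sequences are uniform over
the 20 amino acids; a trace is simulated from a chosen window by applying
the noise model: a per-position ambiguity probability (default 0.10), a
per-position under-calling probability that depresses the observed class
by one (default 0.05 — only ever downward, matching how disorder
truncates density and keeping simulations consistent with the one-sided
exclusion rule), gap regions at an expected rate of one per 50 residues
whose reported `n` is the true length plus a small perturbation clamped
so the truth always stays admissible, and optional completely-missing
breaks. Defaults for quantities the procedure itself does not fix were
chosen once as representative of interpreting a ~3.5 Å map — e.g. traced
windows of 60 residues, gap true lengths of 3–6 residues with reported
error `x = 2`, 20-protein decoy proteomes spanning 100–400 residues — and
are not tuned per experiment.

What the generator does *not* emulate: real proteome composition biases,
correlated noise along helices or strands, systematic mis-tracing of the
main chain, and any map-space effects (B-factors, anisotropy). Passing
the recovery benchmarks therefore demonstrates the correctness and
discriminative power of the scoring/search machinery under the stated
noise, not field performance on any particular map.

`recovery_harness()` runs the full loop — proteome, window, noisy trace,
screen, decide — and reports the rank-1 recovery rate and the
margin-assignment rate. With zero noise, recovery is exact by
construction (and asserted in 100/100 seeded runs); under the default
noise model the suite requires rank-1 recovery in ≥95/100 and correct
assignment in ≥80/100 seeded runs. Problem sizes in the shipped tests
(1000 oracle-equivalence instances of a few-to-~20 trace positions
against 15–40-residue candidates, two-segment cases kept smaller because
the brute-force placement count multiplies across segments; 100-run
harnesses) were chosen to exercise the search space thoroughly while
keeping the default suite quick to run.

## Capsid bookkeeping

The `capsidmath` functions collect the icosahedral arithmetic used when
interpreting a whole capsid:

* `capsid_census()` scales per-asymmetric-unit copy numbers by the 60
  icosahedral asymmetric units; `pbcv1_census()` encodes the PBCV-1
  stoichiometry (28 pseudo-hexamers × 3 MCP chains, 1 penton chain, 13
  minor proteins), giving 5040 + 60 + 1800 = 6900 chains.
* `t_number_from_chains()` inverts jelly-roll conservation,
  `60·T = 2·MCP + 1·penton`, giving T = 169 for PBCV-1;
  `hk_candidates()` enumerates the Caspar–Klug lattice vectors
  (`h² + hk + k² = T`; for 169: (13, 0) and the chiral pair (8, 7)).
* `symmetron_capsomer_count()` and `triangular_count()` give the 66- and
  31-capsomer symmetron totals and the 36-capsomer (8-per-edge)
  triangular sub-array, all mutually consistent with the census.
* `tape_measure_estimate()` scales the 473-residue shell-contacting span
  of the PBCV-1 tape-measure protein (190 nm capsid) linearly with
  diameter: ~1250 residues at 500 nm, ~750 at 300 nm. Presentation
  rounds to the nearest 50 by default (the granularity at which such
  extrapolations are honestly quotable); the raw estimate is always
  returned alongside.
* `sequon_scan()` reports, for every Asn, whether it sits in a canonical
  N-X-(T/S) sequon and whether a small residue (Ala/Gly) precedes it.
  The sequon rule is applied literally as N-X-(T/S) with unrestricted X;
  the common X ≠ P refinement is *not* imposed, because the observation
  of interest here is precisely that several genuinely glycosylated
  sites fail even the permissive rule while sharing the small preceding
  residue.

## Numerical and degenerate-input choices

* Scores are compared with an absolute tolerance of 10⁻¹² when deciding
  ties; all arithmetic is on small sums of table entries, so this is far
  below any meaningful difference.
* A trace whose every position is ambiguous has an undefined mean and is
  excluded as `no_scored_positions` rather than given a default score.
* A gap's lower bound is floored at 0; a zero-length gap is admissible
  only when `n − x/2 ≤ 0`.
* Inter-segment missing regions may have length 0 (segments may abut):
  the weakest constraint consistent with "no information".
* Residue ranges are 1-based inclusive throughout the capsid functions;
  trace/alignment offsets are 0-based, and each is documented where it
  appears.

## Limitations

The package identifies sequences from *already traced* density; it does
not read MRC volumes, build or refine coordinates, or predict secondary
structure and transmembrane topology (external validations in the
original workflow). The default size/score tables are principled
stand-ins, not the map-derived calibration; users with access to the real
tables should load them via `load_config()`. Exhaustive search is
exponential in the number of gap regions per segment — appropriate for
manually built traces, not for genome-scale gapped alignment.
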