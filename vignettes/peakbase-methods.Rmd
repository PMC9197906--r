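---
title: "peakbase: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{peakbase: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakbase)
```

`peakbase` is a local spectral knowledge-base engine: a compound registry,
a multi-technique spectrum store, a curation workflow and a search layer,
with community-format I/O. This vignette documents the scientific
conventions the engine commits to, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices a maintainer should know about.

## The ion mass calculus

Masses are computed from a frozen element table (`element_masses()`):
monoisotopic masses are the NIST masses of each element's most abundant
isotope (carbon exactly 12 by definition of the unified atomic mass unit);
average masses use abundance-weighted atomic weights (NIST isotopic
compositions for CHNOPS, IUPAC standard values for the rest). Freezing the
table in code, rather than consulting a toolkit at run time, makes every
mass in a store reproducible offline; the cost is that atomic-weight
revisions require a package update, which is acceptable for the fourth
decimal place stability this application needs.

An adduct annotation follows the community bracket notation
`[kM ± species …]z±` — multimer count `k`, one or more signed neutral
species (`+H`, `+Na`, `-H2O`, `-2H`…), charge magnitude `z` and polarity.
`theoretical_mz()` evaluates

$$ m/z \;=\; \frac{k\,M + \sum_i s_i\,m_i \;-\; p\,z\,m_e}{z} $$

with the electron mass $m_e$ = 0.000548580 Da subtracted (positive mode) or
added (negative mode) per charge. The electron term is not cosmetic: it is
0.00055 Da, i.e. ~2.2 ppm at m/z 250, which matters whenever sub-5-ppm
claims are made at the conventional 4-decimal m/z display. With the
correction, `[M+H]+` adds exactly one proton
($m_H - m_e$ = 1.007276 Da):

```{r}
mz <- theoretical_mz("C14H18N2O2", "[M+H]+")   # protonated hypaphorine
round(mz, 4)
mz - monoisotopic_mass("C14H18N2O2") - mass_constants()$proton_mass
```

The formula grammar accepts one level of parentheses with an integer
multiplier (`CH3(CH2)2OH`); deeper nesting is rejected deliberately —
it is rare in small-molecule work and a one-level grammar keeps parse
errors locatable (messages carry the offending token and position).
Element symbols are case-sensitive (`Co` ≠ `CO`). Canonical serialization
is Hill order: C, H, then the remaining symbols alphabetically; without
carbon, all symbols alphabetically.

InChIKey validation is syntactic only (the 14–10–1 uppercase hyphenated
layout), with rejection reason codes (`bad_length`, `bad_hyphenation`,
`bad_charset`). Verifying that a key actually hashes the supplied InChI
requires a full cheminformatics toolkit; that check belongs to an optional
enrichment provider, not the core engine, which must run with no chemistry
stack installed.

## Compound registry and curation semantics

The InChIKey is the identity key: one card per key, always. Re-importing a
known key merges: incoming names join as synonyms with score 0, and stored
masses, formula, InChI, SMILES and molfile are never recomputed or
overwritten on merge. The asymmetric cross-reference rule deserves
emphasis: an identifier for a bank with nothing stored is adopted silently
(it is an addition, not a conflict), while a *different* identifier for an
already-populated bank leaves the stored value intact and posts an
`EXTERNAL_ID_CONFLICT` curation message carrying both values. Conflicts
are not deduplicated — resolving a message and re-importing the same clash
opens a fresh one — because a repeated conflict is fresh evidence that an
upstream source still disagrees.

Curation state is a 1–5 star grade (1 = freshly imported, 5 = fully
validated); the endpoints are the meaningful contract, the intermediate
grades are lab policy. Name ranking is manual: scores 0–10, the primary
name is always a maximal-score name with ties broken by insertion order.
`promote_primary()` raises the promoted name's score to the current
maximum — the only way to promote a lower-scored synonym without violating
the primary-has-max-score invariant. Star changes, MSI-level changes and
peak-annotation edits are appended to an audit trail.

Roles are a deliberately simple three-tier check (`user`, `curator`,
`admin`): grading, name scoring, MSI levels and message resolution require
curator or admin; posting messages and annotating peaks require any
authenticated user. There are no per-object ACLs.

Enrichment (extra synonyms, logP, endogenous status, completing a missing
InChIKey from a name) is behind a provider function; the default
`offline_provider()` returns "unknown" for everything, so the engine never
needs network access. A provider backed by web services can be substituted
without touching registry code.

## Spectrum cards and metadata groups

Techniques cover LC/FIA/GC/IC mass spectrometry (full-scan and
fragmentation) and 1D/2D NMR. Each technique mandates a set of metadata
groups (`metadata_requirements()`): all spectra need a sample group; LC
techniques a liquid-chromatography group; GC/IC their chromatography
groups; all MS an ionization method (with polarity) and an ion analyzer;
NMR an instrument group (field strength, pulse sequence). The *group*
applicability is fixed by technique; the minimal mandatory *fields* inside
each group are intentionally small and overridable via the `requirements`
argument of `validate_metadata()`, because sensible mandatory field lists
are site policy (one lab's mandatory gradient table is another's free
text). A group that does not apply to the technique is itself a validation
error, which is what catches a GC-MS import carrying LC metadata.
Sample-preparation detail is stored as free text in the sample group — no
structured preparation schema is attempted. Fragmentation spectra may
carry one `(precursor_mz, collision_energy)` pair in the ionization group;
there is no fragmentation-tree model.

Peaks are normalized at registration: sorted by m/z (MS) or chemical shift
(NMR), relative intensities computed as `round(999·I/Imax)` on the 0–999
MassBank convention (scale-invariant by construction). 2D NMR cross-peaks
are stored as F1/F2 shift pairs with an optional assignment — no volume
model. Sample types are the four-way classification `chemical_standard`,
`standard_mix`, `reference_matrix`, `biological_matrix`; the first two
require at least one compound link.

Annotated MS peaks get theoretical m/z and ppm auto-filled only when the
card links exactly one compound; on a standard mix the neutral molecule is
ambiguous and the annotation is stored verbatim. MSI
identification-confidence levels (1–4) live on the spectrum–compound link,
not on the card: confidence is a property of one pairing.

## SPLASH

`compute_splash()` implements SPLASH v1 for MS peak lists:
`splash10-<4>-<10>-<20>` where block 2 is a wrapped 10-bin, 5-Da, base-3
intensity histogram of the ten most intense ions re-encoded in base 36;
block 3 a wrapped 10-bin, 100-Da, base-10 histogram of the full spectrum;
block 4 the first 20 hex characters of the SHA-256 digest of the canonical
peak string (ions sorted by m/z then intensity, fixed-point `mz·10⁶` and
integer-truncated intensity, 1e-7 epsilon before truncation). Two details
are this package's documented dialect where published accounts of the
reference code differ: top-10 ties are broken by ascending m/z (keeping
the prefilter block permutation-invariant), and no base-peak-percentage
cut is applied before the prefilter histogram. The test suite pins the
implementation to frozen vectors from an independently written port of the
algorithm and asserts determinism and permutation invariance on random
peak lists.

SPLASH is computed for **all** MS techniques, not only LC-MS: hashing is
free and uniform hashing helps cross-technique deduplication. NMR spectra
get no SPLASH (the published algorithm is defined over m/z spectra).

## Search semantics

All search operations are contractually equal to a brute-force linear scan
— the acceptance suite asserts exact set equality on randomized stores —
so indexing remains a private optimization. Conventions: tolerance
boundaries are inclusive (a peak exactly at `target ± tol` matches);
quick-search numeric queries use a ±0.01 Da monoisotopic-mass window; name
matching is case-insensitive substring, with no stemming or fuzzy layer
(free-text "natural language" interpretation is out of scope; structured
filters are the query language). Quick-search ranking is fixed: exact
pf_id, exact InChIKey, primary-name hit, synonym hit, mass-window hit.
Peak searches sort by |Δ|; m/z tolerances come in ppm or Da; chemical-shift
windows are plain ppm-of-shift values. For 2D NMR the target matches
either axis unless pinned to F1 or F2; 1D spectra are excluded when a
dimension is pinned, since they have no F1/F2 axes.

## I/O formats

Export dialects: RFC-4180 CSV for compound tables; SDF as molfile plus
`> <tag>` data items (cards without a stored structure get a zero-atom
V2000 stub flagged as such in its comment line); MassBank 2.x field names
with optional fields omitted rather than emitted empty; NIST MSP; and an
nmrML-lite XML subset (acquisition field strength, sample solvent/pH, 1D
peak list) that does not claim full nmrML schema conformance. Peak tables
are written sorted by ascending m/z. Every writer has a reader and
`read(write(x))` is asserted over randomized cards for all exported
fields. Spectrum templates are directories of CSV sheets named after the
import sheets (sample / chromatography / MS_analyzer / GCMS_analyzer /
NMR_analyzer / Other + peaks + compounds) — plain text diffs and
fixture-friendly, where a spreadsheet workbook would be binary. The sheet
set must match the technique declared in the sample sheet; a bundle with
both an MS and an NMR analyzer sheet is rejected as ambiguous. Numbers in
text exports are printed at 15 significant digits; raw-data payloads are
out of scope throughout (the store keeps metadata about raw files, not the
files).

## Interfaces

The CLI (`pkb_cli()`, wrapped by `inst/cli/peakbase`) persists the store as
a JSON snapshot between invocations (exact round-trip, 17-digit doubles).
Exit codes: 0 success, 1 user error, 2 internal. The JSON programmatic
interface is implemented as the transport-agnostic handler `api_handle()`
— bearer-token gate (401), 404 for unknown ids, an OpenAPI 3.0 description
at `/openapi.json` — with `serve_api()` binding it to HTTP only when the
optional httpuv package is present. CLI `--json` output and API bodies are
produced by the same conversion (`card_to_list()` + one serializer
configuration), so the two surfaces are byte-identical after key-ordering
normalization; a test asserts this. Write operations are CLI/R-only in
this version; the HTTP surface is read-only, with static bearer tokens
from configuration.

## The synthetic-data generator

`generate_compounds()` / `generate_spectra()` emulate a demonstrator-scale
library — the defaults, 96 compounds and 400 spectra, mirror the scale of
a curated reference collection assembled across FIA, reversed-phase and
HILIC LC-MS and NMR platforms — without reproducing any real library's
content. Pseudo-InChIKeys are format-valid but **not** chemically derived;
they carry the marker block `SYNTHKEYSA` so they can never be mistaken for
real identifiers. Formulas are plausible CHNOPS draws (C 4–30, H ≈ 1.6·C,
occasional N/O/S/P); two fixed anchor rows (hypaphorine C14H18N2O2,
L-tryptophan C11H12N2O2) support the worked examples. MS spectra plant
2–3 peaks at the theoretical m/z of common adducts (`[M+H]+`, `[M+Na]+`,
`[M+H-H2O]+`; chloride/deprotonation analogues in negative mode) with
Gaussian m/z noise of `noise_ppm` ppm (default 0) rounded to 6 decimals,
and log-normal intensities; 1H shifts are uniform on 0–10 ppm, 13C on
0–200 ppm. The technique mix defaults to 65% MS / 25% 1D NMR / 5% 2D,
weighted toward LC-MS as in typical metabolomics platforms.

What the generator does **not** emulate — and therefore what passing tests
do not certify about real data: isotope patterns, fragmentation chemistry
(MS2 peaks are adduct placeholders, not fragments), retention-time
structure, correlated NMR multiplets, instrument-specific mass-accuracy
drift, and real chemical name distributions. The generator validates the
engine's bookkeeping and search contracts, not annotation performance on
experimental spectra.

## Numerical choices and problem sizes

Masses are stored at full double precision; 4-decimal m/z and 2-decimal
average-mass rounding is display convention only. The generator rounds
planted m/z to 6 decimals, which keeps a noise-free planted peak within
0.01 ppm of theory at m/z 100 and guarantees exact text round-trips at the
15-significant-digit printing used by the writers. Peak order ties (equal
m/z) are broken by intensity; name-score ties by insertion order; SPLASH
top-10 ties by ascending m/z. Empty compositions have mass 0; empty peak
lists are rejected for MS registration and for SPLASH.

The property suites run at sizes chosen to exercise the contracts while
keeping a full check fast on one CPU: 1,000 randomized import orders of a
9-row batch for deduplication, 50 randomized stores (≤ ~50 spectra each)
for search-oracle equality, 50 cards per format for round-trips, 100
random peak lists plus 20 frozen vectors for SPLASH, and one
96-compound/400-spectrum end-to-end run in which every planted adduct peak
must be recovered by a 5 ppm search.

## Known limitations

No isotope-pattern simulation or charge-state deconvolution; no
full-spectrum similarity scoring (dot product / spectral entropy); no
structure interconversion (SMILES ↔ InChI) or drawing; no tautomer or
stereochemistry reconciliation beyond InChIKey equality; no mzML/raw
parsing (peak lists are supplied already cleaned); 2D-NMR export formats
are not provided (2D peaks live in cards and template bundles only); the
HTTP layer is optional and read-only.
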