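# peakbase

A local, embeddable spectral knowledge-base engine for metabolomics.

Metabolite annotation hinges on curated reference libraries: collections of
compound records and of mass-spectrometry / NMR reference spectra acquired
on local instruments, searchable by mass-to-charge ratio or chemical shift
at a stated tolerance. Public repositories cover only part of any lab's
chemical space and none of its in-house acquisitions, so groups need a
library engine they can run themselves. `peakbase` provides that engine as
an R package: a compound registry keyed by InChIKey, multi-technique
spectrum cards with typed metadata, a curation workflow, tolerance-based
search, community-format import/export, a deterministic fixture generator,
a command-line interface and a JSON programmatic interface. It is aimed at
analytical chemists and bioinformaticians maintaining local spectral
libraries, and at pipeline authors who need library search as a component.

## What the engine computes

**Ion mass calculus.** Every compound card stores a molecular formula; the
monoisotopic mass is `M = Σ nᵢ mᵢ` over the most-abundant-isotope masses of
its atoms (frozen NIST values, `monoisotopic(C) = 12` exactly). An adduct
annotation `[kM ± s₁ ± s₂ …]z±` maps to the theoretical mass-to-charge
ratio

    m/z = (k·M + Σ sign(sᵢ)·m(sᵢ) − p·z·mₑ) / z

with polarity `p = ±1`, charge magnitude `z` and the electron mass `mₑ`
included, so `[M+H]+` adds exactly one proton. Observed peaks are compared
by the signed relative error `ppm = (obs − theo)/theo × 10⁶`.

**Identity and deduplication.** Compounds are unique per InChIKey. A
re-imported key is merged, never duplicated: new names become score-0
synonyms, stored masses and structure are left untouched, and a conflicting
external identifier (e.g. two different ChEBI ids) raises a typed curation
message instead of an overwrite. Curators grade cards with 1–5 stars, rank
names, and record MSI identification-confidence levels (1 = confirmed
against an authentic standard … 4 = unknown) on spectrum–compound links.

**SPLASH.** Every mass spectrum gets a SPLASH hash — the order-invariant
spectral identifier used for cross-database matching
(`splash10-<prefilter>-<histogram>-<sha256/20>`).

**Search.** Quick search (id / InChIKey / name substring / mass window),
AND-OR filter trees, and inclusive-boundary peak search by m/z (ppm or Da
tolerance) or chemical shift (ppm window, per-axis control for 2D NMR).

**Formats.** Compound batch CSV, compound CSV/SDF export, MassBank record
and MSP export for MS spectra, an nmrML-lite XML subset for 1D NMR, and
directory-of-CSV spectrum template bundles, each with a matching reader
that round-trips the exported fields.

## Worked example

A recurrent unidentified LC-HRMS signal at m/z 247.1453 in a plasma matrix,
putatively annotated as protonated hypaphorine (C14H18N2O2):

```r
library(peakbase)
store <- new_store()

card <- register_compound(store, list(
  common_name = "hypaphorine",
  inchi = "InChI=1S/C14H18N2O2/synthetic-fixture",
  inchikey = "HYPAPHORINESYN-SYNTHKEYSA-N",   # synthetic fixture key
  formula = "C14H18N2O2"
))
card
#> <compound card> PFc000001  hypaphorine
#>   formula C14H18N2O2  monoisotopic 246.1368  average 246.31
#>   InChIKey HYPAPHORINESYN-SYNTHKEYSA-N  stars 1

spec <- register_spectrum(store, list(
  technique = "LC-MS", sample_type = "biological_matrix",
  compound_links = list(list(compound = card$pf_id)),
  metadata = list(
    sample = list(label = "NIST plasma, positive mode"),
    liquid_chromatography = list(column_name = "C18 100x2.1", flow_rate = "0.3 mL/min"),
    ionization_method = list(ionization = "ESI", polarity = "+"),
    ion_analyzer = list(instrument = "Orbitrap")
  ),
  peaks = data.frame(mz = c(247.1453, 188.0706), intensity = c(999, 142))
))

# peaks are stored sorted by m/z; annotate the base peak (row 2)
spec <- annotate_peak(store, spec$pf_id, 2, "[M+H]+", actor = "curator")
spec$peaks
#>         mz intensity relative_intensity annotation theoretical_mz      ppm
#> 1 188.0706       142                142       <NA>             NA       NA
#> 2 247.1453       999                999     [M+H]+       247.1441 4.838156

# record the putative identification (MSI level 2: spectral match, no standard yet)
set_msi_level(store, spec$pf_id, card$pf_id, 2, actor = "curator")

search_peaks_mz(store, 247.1441, mass_tolerance(5, "ppm"))
#>       pf_id peak       mz intensity  delta      ppm
#> 1 PFs000001    2 247.1453       999 0.0012 4.855467
```

The annotated peak's theoretical m/z, 247.1441 at the 4-decimal display
convention, is the protonated-hypaphorine reference value; the observed
signal sits 4.9 ppm away and is recovered by a 5 ppm search but not by a
3 ppm one. Once an authentic standard is acquired and registered, the link
is upgraded to level 1 with the same call.

The same store drives the CLI (`inst/cli/peakbase`):

```sh
peakbase --store lib.json init
peakbase --store lib.json import compounds my_compounds.csv
peakbase --store lib.json search mz 247.1441 --tol 5ppm --json
```

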