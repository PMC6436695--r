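---
title: "Exact-mass annotation of Nod factors: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact-mass annotation of Nod factors: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcoms)
```

# The identification model

Nod factors (lipochitooligosaccharides, LCOs) are screened by targeted
high-resolution LC-MS/MS: every precursor ion observed in positive mode is
compared against a combinatorial database of candidate structures, and an
identification is accepted when three independent lines of evidence agree.

1. **Exact mass.** The observed precursor m/z must lie within a ppm
   tolerance of a candidate's theoretical adduct m/z,
   $\mathrm{ppm} = (m_\mathrm{obs} - m_\mathrm{theo})/m_\mathrm{theo}\times 10^6$.
   The default tolerance is 5 ppm, the usual operating point of an
   orbitrap acquisition at resolution 70000.
2. **Isotope envelope.** The observed isotope envelope must resemble the
   candidate's theoretical envelope. We score the resemblance as
   $100 \times \cos\angle(\mathbf a, \mathbf b)$ between the two abundance
   vectors aligned on the nominal-offset grid, and gate at 80 by default.
   Vendor software reports a proprietary "isotopic pattern score" with the
   same gate; cosine similarity is the standard open equivalent and is
   monotone in envelope agreement, which is all the gate requires.
3. **Fragments.** When the acquisition selected the precursor for
   fragmentation, at least one predicted glycosidic B/Y ion must appear in
   the MS2 spectrum within a (looser) fragment tolerance, 10 ppm by
   default. Precursors without MS2 are judged on mass and envelope alone;
   requiring fragment evidence *only when MS2 exists* reflects how
   data-dependent acquisition actually samples precursors, where low
   intensity, not low confidence, keeps a compound out of the MS2 queue.

Accepted hits are deduplicated per *isomer group* — candidates sharing an
elemental formula, which precursor mass cannot distinguish — keeping the
smallest |ppm| error (ties: higher isotope score, then lexicographic name).

# From name to formula

Structures are written in the compact Spaink convention: Roman-numeral
backbone length, acyl chain `C<carbons>:<unsaturations>`, then substituent
flags, e.g. `V (C18:1, NMe, S)`. The elemental formula follows fixed
composition rules:

* backbone of $n$ GlcNAc residues: $n \times \mathrm{C_8H_{15}NO_6} -
  (n-1) \times \mathrm{H_2O}$;
* acylation replaces the non-reducing terminal acetyl
  ($\mathrm{C_2H_3O}$) with the fatty acyl group
  $\mathrm{C_cH_{2c-1-2u}O}$;
* substituent deltas: NMe $+\mathrm{CH_2}$, S $+\mathrm{SO_3}$,
  Cb $+\mathrm{CHNO}$, Hex $+\mathrm{C_6H_{10}O_5}$,
  dNAc $-\mathrm{C_2H_2O}$.

The rules commute, so the formula is independent of the order in which
decorations are applied, and dNAc positional isomers share one formula by
construction.

```{r formula}
s <- parseStructure("V (C18:1, NMe, S)")
formulaString(elementalFormula(s))
adductMz(s, "M+H")
```

**Residue numbering.** The printed nomenclature does not say from which end
"residue 3" of a de-N-acetylation is counted. We number from the
non-reducing (acylated) terminus, residue 1 being the acylated residue —
the end the biosynthetic acyl transferase defines unambiguously. Residue 1
can never carry a dNAc (its acetyl is already replaced by the acyl chain),
and the choice has no mass consequence: positional isomers are isobaric.
It only affects which side of a glycosidic cleavage the modification
travels with.

**Fragment routing.** For cleavage at bond $i$ (from the non-reducing
end), the B$_i$ ion keeps residues $1..i$ as an oxocarbenium
(hydrolyzed-fragment mass $-\mathrm{H_2O}$ + adduct) and Y$_{n-i}$ keeps
residues $i+1..n$ (hydrolyzed-fragment mass + adduct). The acyl chain and
NMe sit on residue 1 and go with B; the sulfate esterifies the reducing
residue and goes with Y. The nomenclature does not localize the carbamoyl
or the extra hexose; we assign Cb to the non-reducing side and Hex to the
reducing side, a documented assumption that affects individual fragment
m/z values but never the complementarity identity
$m(\mathrm B_i) + m(\mathrm Y_{n-i}) = M + 2\delta$, which the test suite
asserts for every inventory structure.

# Isotope envelopes

Envelopes are computed on the *aggregated* (unit-mass) grid: each element
contributes the distribution of its total neutron offset (multinomial over
its isotopes), and element distributions are convolved. Fine isotope
structure (the few-mDa splittings within one nominal peak) is deliberately
not modelled — at resolution 70000 the isotopologues of a 1-1.5 kDa LCO
coalesce into single envelope peaks. Four envelope peaks are scored by
default; beyond the fourth peak the theoretical abundance of these
formulas is ~1% and instrument noise dominates. The convolution is checked
in the tests against an exhaustive enumeration over all isotope
assignments for small formulas (absolute error < 1e-9).

```{r pattern}
isotopePattern("C56H97N5O26")
```

# The candidate database

The default enumeration spans backbones of 3-5 residues, acyl chains
{14:0, 16:0, 16:1, 18:0, 18:1, 20:0, 20:1}, every subset of
{NMe, S, Cb, Hex} with S and Cb mutually exclusive (no known LCO carries
both), and dNAc variants at the internal residues (2-4) of pentamers —
504 candidates, all 36 inventory structures among them. The configuration
is data, not code: screening databases in this field are assembled from
strain-specific prior knowledge, and published counts (a thousand-odd
compounds for broad-host-range strains) reflect enumeration rules that are
not fully specified anywhere; we therefore treat the candidate space as a
user-editable configuration rather than attempting to reproduce any
particular published database size.

# The synthetic-data generator

The paper-level experiment this package benchmarks against never deposited
raw spectra, so the generator is a first-class module that defines the
study conditions rather than a throwaway fixture. For each planted
structure it draws an adduct (M+H 80% / M+Na 20% — protonated species
dominate positive-mode DDA), jitters the precursor m/z uniformly within
±2 ppm (uniform *in ppm*, mirroring the tolerance metric), distorts the
theoretical envelope multiplicatively with log-normal noise
(σ = 0.05), and draws log-normal intensities. Decoys are formula
perturbations (±CH2, ±O) of random candidates, accepted only if ≥ 20 ppm
from *every* database m/z — realistic near-misses that must never be
annotated at a 5 ppm tolerance; construction fails loudly if the candidate
space is too dense for the requested floor. Noise precursors appear at a
Poisson rate with shapeless 3-peak envelopes. Precursors are shuffled into
an elution order, grouped into MS1 cycles of 8 co-eluting species, and the
5 most intense per cycle (TOP5) receive MS2 spectra: the structure's B/Y
ions with the same ppm jitter plus a few random fragment peaks. All
randomness flows from one seed, and the generator returns its ground truth
alongside the run.

What the generator does **not** emulate: chromatographic peak shape and
retention order, realistic dynamic range and detector saturation,
co-isolation chimeras, in-source fragmentation, or adduct coelution for a
single compound. Passing the end-to-end benchmark therefore demonstrates
the correctness of the matching, scoring and bookkeeping machinery under
calibrated mass error and envelope noise — not robustness to every failure
mode of real chromatography.

**Presence accounting.** Precursor mass cannot separate positional
isomers, so crediting an isomer-group hit to *all* group members would
over-count against a ground truth that planted only some. The presence
matrix therefore supports two documented modes: `provenance` (synthetic
benchmarks; group hits credited only to planted members) and `mass-only`
(real data; every inventory member of the group is marked). The mode is
recorded in the object and in the pipeline's JSON summary.

```{r pipeline}
res <- runPipeline(seed = 42, quiet = TRUE)
colSums(detected(res$matrix))
```

# The DEG stage

The package does not re-estimate differential expression (that belongs to
DESeq2 and friends); it consumes per-gene statistics and applies the
definition used in the source experiments: a gene is differentially
expressed when its *signed* fold-change (ratio $r$ reported as $r$ when
$r \ge 1$, as $-1/r$ otherwise) satisfies $|FC| \ge 2.5$ **and** the
Benjamini–Hochberg adjusted p-value is ≤ 0.05. Choices worth recording:

* The threshold is *inclusive* (≥). The verbal definition ("lower or
  higher than") does not settle strict vs inclusive; inclusive is adopted
  and documented, and with continuous fold-changes the difference is
  measure-zero.
* Tables shipping log2 fold-changes are auto-detected — finite nonzero
  values inside (−1, 1) are impossible under the signed convention — and
  converted, with a message.
* Genes with missing adjusted p are excluded (with a logged count),
  mirroring how DESeq2 reports filtered genes.
* BH adjustment delegates to `stats::p.adjust(method = "BH")`; the test
  suite verifies it against a direct step-up implementation on a thousand
  random vectors.

The synthetic DE generator allocates 6289 genes to the four replicons by
CDS count (3672 / 212 / 500 / 1905) and plants per-replicon up/down
counts. The default planting reproduces the study's totals — 743 DEGs,
461 up; 468 on the chromosome (333/135), 67 on the symbiotic plasmid
(66/1), 36 on plasmid c (19/17). Those published per-replicon counts sum
to 571, not 743; the residual 172 DEGs (43 up / 129 down, forced by the
totals) are assigned to plasmid a so that every printed total is honored
simultaneously. Null genes draw ratios log-normally (σ_log = 0.1) around
1 — their signed fold-changes essentially never reach 2.5, so the joint
filter recovers exactly the planted set.

```{r deg}
deg <- filterDEG(simulateDEGTable(seed = 42)$table, quiet = TRUE)
nrow(deg)
repliconSummary(deg)
```

# Numerical choices and degenerate inputs

* Constants are pinned in a versioned table (NIST/CIAAW isotope masses and
  abundances, IUPAC conventional atomic weights); proton mass
  1.007276466 Da; the M+Na delta is the sodium cation (Na minus one
  electron), 22.989218 Da.
* Envelope spacing uses the 13C-12C difference (1.0033548 Da), and
  observed envelopes are re-gridded by rounding m/z differences to the
  nearest integer offset — safe at ppm-level jitter.
* Formula subtraction refuses to underflow below zero atoms; decoy
  perturbations that would do so are simply retried.
* Empty inputs are legal where they are meaningful (empty annotation sets
  give all-false presence matrices; an empty DE table filters to itself)
  and errors where they are not (empty inventory, empty candidate
  database).
* Matching uses a mass-sorted index with a `findInterval` window; the
  tests assert exact agreement with an all-pairs scan.

# Problem sizes

The shipped benchmarks run at desk scale by choice: a 504-candidate
database, four runs of 4-36 planted structures with 20 decoys each, a
hundred-seed recovery study of 8 planted structures per seed, and DE
tables of the genome's 6289 genes. These sizes exercise every code path —
isomer collisions, decoy rejection, top-N selection, BH ties — while
keeping the full suite fast enough to run on every change.

# Known limitations

* Charge states ≥ 2, cross-ring (A/X) fragments, and mzML input are out of
  scope; peak lists enter as MGF or the documented CSV dialect.
* Retention time is ignored throughout — no RT library exists for these
  compounds in the source experiments.
* Mass-only identification cannot resolve positional isomers; real-data
  runs must use mass-only presence accounting and interpret isomer groups,
  not individual structures.
* The candidate enumeration is a configuration, not a claim about any
  published database's exact contents.
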