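---
title: "Simulating yGG and VEGAS pathway assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating yGG and VEGAS pathway assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegassim)
```

This vignette is the package's account of what it models, which
assumptions it makes, and where the design was genuinely open.

## The model

The toolkit simulates a two-tier DNA assembly workflow for yeast.

In the first tier, standardized parts are joined into transcription
units (TUs) by one-pot type-IIS digestion–ligation (yeast Golden Gate,
yGG). A type-IIS enzyme such as BsaI (GGTCTC) cleaves outside its
recognition sequence — the top strand 1 bp downstream, the bottom 5 bp
— leaving 4-nt 5′ overhangs whose sequence is chosen by the designer.
The package models a cut as a pair of scission coordinates *(t, b)* on
the top strand (0-based, half-open intervals throughout); the interval
between them is the overhang, reported in top-strand orientation
together with which strand protrudes. Two ends ligate exactly when
their top-strand 4-mers are equal with opposite protruding strands —
equivalently, when the physical single strands are reverse
complements. A fixed junction grammar (CCTG, CAGT, AATG, TGAG, TTTT,
AACT) orders vector, left adapter, promoter, CDS, terminator and right
adapter; the 4-mers are pairwise distinct and free of reverse-
complement collisions, which is what makes the one-pot reaction
converge on a single product.

Rather than simulating the cycling reaction kinetically, `simulate_ygg()`
models its end state: every molecule is digested, any fragment still
carrying a recognition site is considered re-cuttable and excluded,
and the simulator searches for circular chains of sticky-end-compatible
fragments that use the acceptor backbone once and each part at most
once. Success requires exactly one such circle; zero or several are
structured errors (open junction, ambiguity). This end-state view is
the right level for design verification: a design whose end state is
ambiguous is wrong regardless of kinetics, and reaction conditions
cannot rescue it.

In the second tier, each TU — flanked by 57-bp VEGAS adapters (VAs)
orthogonal to the host genome — recombines with its neighbours and a
linearized assembly vector through terminal sequence homology.
`simulate_recombination()` builds a directed graph over the backbone
(orientation fixed) and every fragment in both orientations, with an
edge wherever the 3′-terminal window of one piece and the 5′-terminal
window of another share an exact substring of at least `min_homology`
bp, then enumerates all circular paths using every fragment exactly
once. All distinct products are returned; the run is considered
correct only if the product predicted by direct string arithmetic from
the design (`designed_pathway_sequence()`) is among them. Homology
edges unused by any product are reported as warnings, because they are
exactly the misassembly channels a wet-lab screen would see as
off-colour colonies.

## Parameters that matter

* `min_homology` (bp, default **30**): the smallest terminal identity
  accepted as a recombination junction. Designed junctions are 57 bp
  (adapter mode) or 50–60 bp (PCR mode: two ~25–30-nt tails), so 30
  admits both with margin while rejecting the short repeats that arise
  by chance between unrelated sequences (longest chance overlap
  between random 1-kb pieces is well under 20 bp).
* `window` (bp, default **150**): how far from each free end homology
  is scanned. Recombination of transformed linear DNA initiates at
  resected termini, so interior repeats far from an end are ignored —
  a documented limitation, not an oversight.
* `tail_len` / `anneal_len` (nt, defaults **30** / **20**): primer
  homology-tail and annealing lengths in PCR mode. Two facing 30-nt
  tails give the 60 bp of junction homology the workflow is built
  around; `tail_len` is capped at the adapter length.
* `k`, `n_concat`, `final_len` (defaults **10**, **6**, **57**):
  adapter design concatenates six rare 10-mers into a 60-mer and trims
  3 bp. `rare_threshold` defaults to 0 (10-mers absent from the
  genome on both strands) and auto-raises with a warning when the
  genome is too dense for the requested pool.
* `n_candidates` (default **10 × n**): the candidate pool ranked by
  genome similarity before the *n* most orthogonal are kept. The
  original procedure's pool size is not recorded; 10× gives the
  ranking something to choose from at negligible cost.

## Numerical and representational choices

* **Coordinates** are 0-based half-open on the top strand everywhere;
  circular molecules report site positions modulo the length and scan
  the origin-spanning window, and each physical site is counted once
  (palindromic recognition sequences report a single, plus-strand
  hit).
* **Fragment top strands partition the parent circle** between
  top-strand scission points, so ligation is concatenation and every
  junction 4-mer appears exactly once in a product — length
  conservation is structural, and tests assert it on randomized
  molecules.
* **Backbone orientation.** Reading the linearized VEGAS vector's top
  strand 5′→3′ runs from the right-arm adapter (VA2) to the left-arm
  adapter (VA1). With released TUs reading CCTG–LVA–...–RVA–AACT on
  the top strand, a forward circular assembly requires the VA1 copy at
  the backbone's 3′ terminus (TU1's leading VA1 anneals there); a
  VA1-first backbone admits no forward circle, because both molecules
  would extend the same direction from the shared block. Which arm is
  drawn on the left is purely a figure convention; the package fixes
  the orientation that assembles.
* **Flap resection.** BsmBI-released TUs carry 4-bp CCTG/AACT ends
  outside the adapter homology. Real recombination trims such
  non-homologous flaps, and so does the simulator; junction records
  report overlap and flap lengths separately, so product length equals
  summed piece lengths minus summed overlaps and flaps (with zero
  flaps in PCR mode, where homology is exactly terminal).
* **Similarity to the genome** (adapter design) is the length of the
  longest substring shared with either strand — deterministic, exact,
  and aligned with the rare-k-mer construction (a candidate built from
  absent 10-mers cannot share 20 bp, since any 20-mer contains a full
  constituent 10-mer; tests assert the ≤ 19 bound). Ties are broken by
  the count of genome-shared 10-mers, then lexicographically.
  Alignment-score metrics would also work but add nothing for exact
  screening. The 3-bp trim is taken from the 3′ end ("terminal" is
  ambiguous; one end had to be chosen, and a flag allows 5′).
* **CDS storage convention.** Because AATG supplies the start codon
  and TGAG a stop, CDS cores are conventionally stored from codon 2 up
  to (not including) the stop. The package does not enforce this —
  cores are opaque — but the junction arithmetic assumes it when
  interpreting products. Marker TUs (KanMX) are opaque PRO-CDS-TER
  blocks spanning CAGT..TTTT.
* **The insert spacer base** between a BsaI site and the junction
  4-mer is "A" by default; it is destroyed on digestion, so the choice
  is inert.
* **Combinatorial counting** defaults to with-replacement across
  slots, matching a pooled reaction in which every slot sees the full
  pool; the distinct-parts mode (falling factorials) is exposed for
  library designs that forbid part reuse. Both modes exceed the
  60,000-variant scale for the 4 × (10 × 5) configuration; the
  with-replacement value is (10 × 5)⁴ = 6,250,000.

## What the synthetic kit emulates — and what it does not

`make_fixture_kit()` generates, deterministically from a seed, a
background genome (50 kb over three contigs by default — large enough
that most 10-mers are absent, the regime adapter design operates in),
part cores at realistic yeast scales (PRO 300–700 bp, TER 150–300 bp,
CDS 600–1,800 bp in codon multiples — configuration choices, not
measured values), a pre-assembled 1.4-kb marker core, acceptor vectors
with the BsmBI and NotI release chemistries, a VEGAS vector with
VA1/VA2 arms, and the three worked designs: the five-TU carotenoid
pathway in adapter-homology mode, the same pathway re-adaptered for
PCR mode, and the six-TU violacein layout whose deliberate VA5 reuse
exercises the off-target warning. Part names reuse standard yeast
labels as aliases; every sequence is synthetic and marked so in FASTA
headers. All cores are scrubbed of the four enzymes' sites by
resampling, and vectors are rebuilt until they carry exactly the
designed site counts.

Passing tests on this kit demonstrate that the *logic* of the workflow
is right: grammar, cut geometry, chain uniqueness, homology routing,
library arithmetic, variant identification. They do not demonstrate
anything about real sequences — a genuine yeast promoter may carry a
BsaI site (the real workflow re-codes these; this package only reports
them), real genomes have repeat structure a uniform random genome
lacks, and no claim is made about transformation efficiency, assembly
fidelity rates, colony phenotypes or product titres, all of which are
wet-lab quantities outside the model. The simulator's ambiguity and
off-target warnings mirror the *existence* of misassembly channels,
not their in-vivo frequencies.

Problem sizes in the shipped tests are chosen for fast, deterministic
coverage: the shared kit uses a 5-kb genome (the genome only matters
for adapter design, which is exercised separately at the full 50 kb),
oracle-equivalence properties run hundreds to a thousand randomized
cases, and the end-to-end combinatorial recovery property runs fifty
full design→assembly→identification round trips.

## Known limitations

* No ligation-fidelity or mismatch model: sticky ends either match
  exactly or not at all; near-cognate overhang misligation is not
  simulated.
* No kinetics, concentrations, or molar ratios; the end-state model
  cannot rank designs by yield.
* Homology detection is exact substring matching; diverged or gapped
  homology does not count, and interior homology beyond `window` of a
  terminus is invisible.
* Background re-circularization of the empty vector (a known source
  of white colonies) is not simulated.
* Degenerate (IUPAC-ambiguous) recognition sites, methylation
  sensitivity, star activity and partial digestion are out of scope;
  the four packaged enzymes have non-degenerate sites.
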