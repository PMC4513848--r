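# vegassim

**In silico yeast Golden Gate (yGG) and VEGAS pathway assembly**

`vegassim` is a design and simulation toolkit for building multi-gene
pathways for expression in *Saccharomyces cerevisiae* with the
VEGAS/yGG standard. It is aimed at synthetic biologists who want to
verify a pathway design before ordering parts or running reactions:
every wet-lab step of the workflow has an exact in-silico counterpart,
so a design that fails here will fail on the bench for a structural
reason you can read off the diagnostics.

## The workflow it models

**Tier 1 — yeast Golden Gate (yGG).** Each gene is a transcription unit
(TU) of five standardized parts: a left VEGAS adapter (LVA), promoter
(PRO), coding sequence (CDS), terminator (TER) and right VEGAS adapter
(RVA). Parts are carried on inserts flanked by inward-facing BsaI
sites. BsaI is a type-IIS "offset cutter": it cleaves outside its
recognition sequence, 1/5 bp downstream, exposing designer 4-nt 5′
overhangs. A fixed junction grammar orders the parts in a one-pot
digestion–ligation reaction into an acceptor vector:

```
vector—CCTG—LVA—CAGT—PRO—AATG—CDS—TGAG—TER—TTTT—RVA—AACT—vector
```

The AATG junction supplies the CDS start codon and TGAG a stop. The
acceptor's RFP dropout cassette is excised on success, and the
simulator reproduces the reaction's end state: fragments still
carrying a recognition site are re-cut and never accumulate, and the
reaction succeeds only if exactly one circular chain of compatible
sticky ends exists.

**Tier 2 — VEGAS.** Each assembled TU is flanked by VEGAS adapters
(VAs): 57-bp sequences orthogonal to the yeast genome. The packaged
table (`va_adapters()`) holds 18 of them; VA1 and VA2 are additionally
encoded on the arms of the linearized VEGAS assembly vector. Pathways
are stitched together *in yeasto* by homologous recombination between
terminal homologies, in either of two modes:

* **adapter homology** — adjacent TUs share a VA (RVA of TU *i* = LVA
  of TU *i+1*), giving 57-bp junctions; TUs are released from the
  acceptor with BsmBI (or NotI/FseI);
* **PCR homology** — every TU gets unique VAs and junction homology is
  added by primers with ~20-nt annealing regions and 30-nt tails
  copying the neighbour's adapter terminus, so adjacent amplicons
  share 2 × 30 = 60 bp. Gene order and orientation can be changed by
  re-priming alone.

The recombination simulator builds a directed overlap graph (exact
terminal homology ≥ `min_homology`, default 30 bp, scanned within
150-bp terminal windows), enumerates every circular path through the
backbone and all fragments, and reports all distinct products plus
any unused homology edges — which is how a duplicated adapter in a
design surfaces as a misassembly warning.

**Adapter design.** New orthogonal adapters are generated the way the
original set was: census the genome's 10-mers (canonical, both
strands), randomly concatenate rare 10-mers into 60-mers, reject any
candidate carrying a BsaI/BsmBI/NotI/FseI site, rank by similarity to
the genome (longest shared substring, either strand), keep the *n*
most orthogonal and trim 3 bp to the final 57-mers.

**Combinatorial libraries.** Pooled PRO/TER parts in the yGG reactions
give combinatorial pathway libraries. With 4 variable TUs each drawing
from 10 promoters × 5 terminators the theoretical complexity is
(10 × 5)⁴ = 6,250,000 variants. `identify_assembled_variant()` is the
in-silico analogue of sequencing a recovered plasmid: it reads the
PRO/TER assignment back from the junction-adjacent part cores.

## Worked example

Six-TU violacein pathway (five pathway genes plus a KanMX marker TU) by
PCR-mediated VEGAS — a seven-piece assembly including the vector
backbone. The fixture kit is fully synthetic and regenerated from the
seed; part names (`vioA`, `pTDH3`, ...) are aliases for synthetic
sequences.

```r
library(vegassim)
kit <- make_fixture_kit(seed = 1)
run <- assemble_pathway(kit$designs$vio_pcr, kit)
print(run)
#> <vegas_run> 6 TU(s); 1 product(s); intended product recovered
#>   ! unused homology edge vioE_TU -> vioC_TU (30 bp): potential misassembly
run$outcome$junctions[[1]][, c("from", "to", "overlap")]
#>                    from                    to overlap
#> 1 vegas_vector_backbone               vioA_TU      30
#> 2               vioA_TU               vioB_TU      60
#> 3               vioB_TU              KanMX_TU      60
#> 4              KanMX_TU               vioC_TU      60
#> 5               vioC_TU               vioD_TU      60
#> 6               vioD_TU               vioE_TU      60
#> 7               vioE_TU vegas_vector_backbone      30
nchar(run$intended_product$bases)
#> [1] 13801
library_complexity(kit$combinatorial)
#> [1] 6250000
```

Reading the output: the six TUs were each assembled by simulated yGG,
released, amplified with 30-nt homology tails and recombined with the
linearized vector into exactly one circular 13.8-kb product whose
interior junctions all carry the designed 60 bp of homology (30 bp at
the two vector junctions, tail-only). The warning flags the layout's
deliberate reuse of VA5 as the RVA of both the marker TU and `vioE_TU`
— a real off-target homology the design tolerates but a screen should
know about.

A thin command-line wrapper over the same functions ships at
`inst/cli/vegassim.R`:

```sh
Rscript inst/cli/vegassim.R fixtures --seed 7 --out kit/
Rscript inst/cli/vegassim.R assemble --design kit/bcar_va.tsv --seed 7 --out pathway.gb
Rscript inst/cli/vegassim.R design-adapters --genome kit/genome.fa --n 18 --seed 1 --out adapters.tsv
```

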