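---
title: "Design rules and validation strategy in crisprIF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design rules and validation strategy in crisprIF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprIF)
```

# The system being modelled

The *Pseudomonas aeruginosa* type I–F Cascade is a four-subunit
(Csy1–Csy4) crRNA-guided DNA-binding complex. For CRISPRa, an activation
domain fused to Csy3 is recruited to a promoter wherever the crRNA spacer
pairs with its protospacer. Three structural facts drive everything this
package computes:

1. **PAM and crRNA geometry.** Csy1 recognises a 5′-CC PAM at the 5′ end of
   the protospacer on the non-target strand. The mature crRNA is an 8-nt 5′
   handle (Csy1/Csy2), the spacer, and a 20-nt 3′ hairpin (Csy4). We take
   the spacer sequence identical to the protospacer on the PAM-carrying
   strand; the crRNA then pairs with the complementary target strand.
2. **Csy3 stoichiometry.** Each Csy3 clamps 6 nt of spacer; across the
   documented 14–50-nt range this gives 3–9 copies, and `csy3_copies()`
   implements the ceiling rule `ceil(L/6)` — the only simple rule consistent
   with both documented endpoints (14 → 3, 50 → 9) and the canonical
   32 → 6. Spacer extension therefore proceeds in multiples of six from
   32 nt (`extend_spacer()`), each step recruiting one more Csy3 (and one
   more activation domain). Lengths beyond 56 nt are accepted with a
   warning, since the longest validated design is 56 nt.
3. **Pairing tolerance.** Every sixth spacer base is flipped out of the
   RNA:DNA duplex (the periodic 5+1 pairing pattern), and PAM-distal
   positions contribute little to binding, while the PAM-proximal seed
   (1–5, 7, 8) nucleates it. The positional mask encodes this.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| PAM | `CC`, 5′ of protospacer | – | Csy1 recognition |
| Spacer length | 32 | nt | canonical type I–F spacer |
| Design range | [−500, −100] | bp, gene-strand, PAM-proximal anchor | region screened upstream of each TSS |
| Optimal window | [−200, −100] | bp | window where activation ranked strongest across tested genes |
| Masked positions | {6, 12, 18, 24–32} | 1-based PAM-proximal | tolerated positions excluded from the effective count |
| Effective-mismatch cap | 4 | mismatches | ≥ 5 non-tolerated mismatches abolish type I interference |
| Promoter half-width | 2000 | bp | off-targets must lie ≤ 2 kb from some TSS |
| Pair spacing | [50, 75] | bp, 5′-most to 5′-most | optimal dual-crRNA separation |
| SpCas9 comparator | 20 nt, 3′ NGG, ≤ 4 mismatches, no mask | – | parallel search for the dCas9 control |

All are configurable through `run_config()`, `position_mask()` and the
`rule_set` constructors; the defaults are the study values above.

Two wordings of the tolerated set circulate: "24–32" versus "25–32 plus
every sixth position". They differ only at position 24, which the
every-sixth rationale includes anyway (4 × 6); we adopt {6, 12, 18, 24–32}
and expose it as a parameter. `classify_position()` keeps the finer
distinction (seed / periodic-tolerant / distal-tolerant / internal) for
reporting.

# Conventions and numerical choices

- **Coordinates** are 0-based half-open on the forward axis everywhere
  inside the package and in emitted BED; human-readable reports in the
  analysis scripts print offsets as signed gene-strand-relative integers
  (negative = upstream). GFF3 input is converted on read.
- **TSS-offset anchor.** Offsets are measured at the PAM-proximal
  protospacer base — the functional seed side — since "bp upstream of the
  TSS" does not by itself fix an anchor. Pair spacing is measured 5′-most
  to 5′-most on the forward axis for the same reason.
- **Window boundaries** are inclusive at both ends ([−200, −100] optimal,
  [−500, −100] design), so a boundary site like −500 is in range and −100
  is optimal.
- **Mismatch substitution rule.** Variant panels substitute the
  Watson–Crick complement of the reference base: deterministic, and
  guaranteed to be a mismatch.
- **Block placement.** The five 6-nt blocks of a 32-nt spacer are anchored
  at position 1 (1–6, …, 25–30), leaving 31–32 uncovered; block placement
  is configurable via `block_len` because the exact register of published
  block panels is not fixed by the text they appear in.
- **N handling.** On input, non-ACGTN characters are normalised to N (a
  strict mode errors instead). In design scans, windows containing N are
  excluded — one cannot order a guide with an undetermined base. In
  off-target scans N counts as a mismatch at every position and never
  satisfies a PAM base, so N-rich regions cannot create spurious hits.
- **Degenerate inputs.** Fewer than two candidates yield an empty pair
  list (not an error); an empty genome or an all-N query is an error;
  `csy3_copies()` rejects spacers under 6 nt, the minimal Csy3 binding
  unit.
- **Tie-breaks** are all deterministic: candidate ranking is a stable sort
  (window class, |offset + 150|, coordinate), pair ranking uses distance
  from the 62.5-bp midpoint of the optimal spacing interval, and the
  promoter filter resolves equidistant TSSs toward the lexicographically
  smaller gene identifier. Re-running any stage on identical inputs
  produces byte-identical files.

# Off-target search design

Both search rules are instances of one `rule_set` record: spacer length,
PAM pattern and side, positional mask, and mismatch cap. The production
enumerator is a PAM-anchored exhaustive scan — only windows whose PAM
matches are Hamming-checked, with vectorised per-position comparisons —
which at desk scale is exact, not heuristic. Its correctness is guaranteed
by equivalence testing rather than by construction: `brute_force_oracle()`
re-implements the contract as a plain position-by-position loop with no
prefilter, and the test suite asserts identical hit sets on 100 seeded
10-kb genomes (plus planted-decoy genomes) for both rule sets.

Off-target candidates are required to carry the PAM by default
(`require_pam = TRUE`): PAM recognition is mechanistically required for
binding. A PAM-agnostic pure similarity search is available by flag, since
published off-target searches are sometimes described only as "sequence
similarity". Promoter overlap means any protospacer base inside the
±2-kb interval; the filter annotates the nearest gene and the signed
strand-relative TSS distance.

`find_overlap_sites()` composes the machinery: it looks for genes whose
design window contains overlapping Cascade and SpCas9 protospacers where
*each* guide also has a surviving off-target in a different gene's
promoter — the site-selection step used to pick targets for off-target
validation experiments.

# What the synthetic data emulates — and what it does not

`generate_genome()` draws i.i.d. bases at GC 0.41 (human-like);
`plant_gene()`, `plant_on_target()` and `plant_decoy()` overwrite the
background with PAM + protospacer copies at controlled TSS offsets and
mismatch patterns, tracking footprints to prevent collisions (100 bounded
retries for random placement, deterministic given the seed) and verifying
that each planted PAM+spacer string does not also occur by chance
elsewhere. The truth manifest records, per feature, its coordinates,
mismatch positions, effective count, and whether the default rules should
detect and retain it — with promoter membership computed from the actual
planted coordinates, so features that land inside a promoter by chance are
scored correctly.

`simulate_dataset()` fixes the study conditions: one on-target per gene at
offset −150 (centre of the optimal window), and per gene a decoy panel
covering the regimes the rules must separate — masked-only mismatches
(effective 0), effective 2 at a random locus, effective 5 (undetectable),
and effective-2 decoys planted 1.5 kb inside and 2.5 kb outside the
promoter. Sample sizes in the tests (20 seeded datasets of 20 kb × 2
genes; 100 oracle genomes of 10 kb; 50-kb genomes for the mismatch-ladder
checks) were chosen as the smallest scales at which every regime of the
rules is exercised on a single CPU.

An i.i.d. background has no repeats, no segmental duplications, no CpG
islands, and promoter sequence with no compositional structure. Passing
the end-to-end suite therefore demonstrates that the *rules* are
implemented exactly — planted truth is classified perfectly — not that
off-target counts on a real genome would be as small or as well separated;
repeat-rich genomes will produce many more near-matches, and chromatin
accessibility (ignored here, as is activity scoring generally) modulates
which bindable sites matter.

# Known limitations

- The direct-repeat sequence shipped by `example_repeat()` is a synthetic
  placeholder with the correct 8 + 20 segment arithmetic; production array
  design requires the user to supply the biological repeat. The 20/8
  cleavage register is the unique split consistent with the stated handle
  and hairpin lengths.
- No activity model: candidates are ranked by window geometry only. The
  optimal window is a heuristic inferred from a small number of genes, not
  a guarantee.
- No bulge/indel off-targets; mismatch-only enumeration.
- Desk-scale search: correct at any size, but not engineered (indexing,
  compressed genomes) for chromosome-scale scans.
- Promoter definition is the plain ±2-kb TSS rule; curated regulatory
  tracks used by genome browsers are richer and not reproduced here.
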