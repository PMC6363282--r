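# epareg — extreme-pathway analysis of metabolic regulatory architecture

Cellular metabolism shifts between steady states, and a productive way to
think about that shift is that the cell switches *extreme pathways* on
and off: the extreme rays of the steady-state flux cone
`{v : S v = 0, v_i >= 0 for irreversible i}` form the unique minimal set
of conically independent routes, and every achievable flux distribution
is a non-negative combination of them. `epareg` ranks the reactions of a
constraint-based metabolic model by how much they matter, on average, for
determining those on/off states — a structural, condition-free prediction
of which reactions are worth regulating (or, in a disease setting, which
reactions are likely disease-associated).

The method, in the field's standard notation:

* Enumerate the extreme pathways of the network (double description over
  the signed flux cone, exact integer arithmetic), classify them (type I:
  primary exchange; type II: currency-only futile cycles; type III:
  internal cycles, discarded), and *compact* them to one signed element
  per reaction.
* Treat each of the `l` surviving pathways as equally likely to be in
  use; reaction `R_i` is "on" in a pathway iff its compact element is
  nonzero. Shannon entropies `H(X)` and conditional entropies
  `H(X1 | X2)` (base 2, exact configuration counts) then quantify what a
  reaction set tells us about the pathway state.
* Merge reactions that determine one another (`H(Ri|Rj) = H(Rj|Ri) = 0`)
  into *EqSets*, optionally refined by the intra-set radius `rho_e` over
  the regulatory distance graph (arc weight = smallest consumer count
  C(M) over shared metabolites; global distance = shortest path).
* Greedily rank the EqSets by regulatory importance
  `val(X) = [1 + mu (|X|-1)] [H(X | N) + min_U H(X | N u U)]`,
  where `N` is the union of recently ranked neighbours within `rho_s`
  (window `tau`) and `U` runs over competing EqSets.
* Score the ranking against literature-documented regulated reactions:
  `sigma` = rank sum of the regulatory EqSets plus a penalty for
  meaningful EqSets that were never ranked, with an exact permutation
  p-value computed by integer dynamic programming.

A subsystem module (duplicate metabolites, M↔M′ link reactions, flux
variability analysis to orient boundary exchanges) makes genome-scale
models tractable by carving out functionally related subnetworks, and a
heuristic coordinate-descent search tunes the four parameters
`(mu, rho_e, rho_s, tau)` over the standard 210,600-tuple grid.

## Worked example: the human red blood cell

The package ships a reconstruction of the classic erythrocyte network
(39 metabolites, 51 reactions, 19 exchange fluxes; glycolysis, the
Rapoport-Luebering shunt, the pentose phosphate pathway, adenine
nucleotide salvage, plus physiological load fluxes) together with the ten
reactions documented as allosterically regulated.

```r
library(epareg)
fx <- hrbcFixture()
res <- runPipeline(fx$network, eqParams(mu = 0.1), meaningful = fx$regulated)
res$pathways
#> PathwayMatrix (extreme_pathway): 59 pathways over 67 split reactions
#>   type I: 40  II: 3  III: 16
res$sequence
#> RankedSequence: 8 ranked internal EqSets, 14 lost
#>    1. Xu5PE, TKI, TA, TKII
#>    2. PGM, EN, PK
#>    3. PRPPsyn
#>    4. PFK, ALD, TPI
#>    5. AMPase
#>    6. G6PDH, PGL, PDGH
#>    7. AK
#>    8. AdPRT
res$score$sigma
#> [1] 55
res$pValue
#> [1] 0.005125559
```

What the numbers mean: the 59 enumerated pathways include the 16
discarded internal two-cycles and 3 ATP-dissipating futile cycles (the
Rapoport-Luebering shunt cycle, the adenosine kinase/AMP phosphohydrolase
cycle, and the PRPP-synthetase salvage loop). The 43 type I+II pathways
group the 32 internal reactions into 22 EqSets (5 with more than one
member), of which 8 contain regulated reactions. The greedy sort ranks
the transketolase/transaldolase group first and six of its eight ranked
EqSets contain documented regulated reactions; the score `sigma = 55`
sums the ranks of the regulatory EqSets (with a penalty for the ones
never ranked), and its exact p-value — the probability that a random
ordering of the 22 EqSets does at least as well — is about `5.1e-3`, so
the entropy ranking recovers the known regulatory architecture far
better than chance. Hexokinase is never ranked, consistent with the weak
control response reported for it.

The pairwise conditional-entropy heat map behind the EqSets is available
as `conditionalEntropyMatrix(res$profile)`; the per-step importance trace
as `sortTrace(res$sequence)`.

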