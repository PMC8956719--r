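---
title: "Scoring parasitoid fitness across two generations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring parasitoid fitness across two generations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clutchfit)
```

## The model

Gregarious egg parasitoids such as the fairyfly *Anaphes flavipes* lay
clutches of 1–4 eggs (exceptionally up to 7) into single host eggs. Larvae
sharing a host divide its resources, so adults from larger clutches emerge
smaller; the species is proovigenic — females eclose carrying their whole
egg complement — and body size maps linearly onto that complement. A
mother's clutch-size decisions therefore fix not only how many offspring
she has (F1 fertility) but how many eggs those offspring can lay in turn
(F2 fertility).

`clutchfit` makes that second-generation accounting explicit. Its central
object is the **fertility table** $f(k)$: the expected egg complement of
one female offspring reared in a clutch of size $k$. A host parasitised
with composition $(k, n_{\mathrm{F}}, n_{\mathrm{M}})$ contributes

$$\mathrm{F2} = n_{\mathrm{F}} \, f(k),$$

males contributing zero by definition (they carry no eggs; their role in
mate finding is outside this model). An allocation of clutches over a host
supply scores as the sum over parasitised **native** hosts. Non-native
hosts — species that accept oviposition but in which larvae cannot
complete development — contribute zero emerged offspring and zero F2 while
still depleting the egg budget; this is how host-community composition
"unintentionally" reshapes realised fitness.

The packaged default table, measured for *A. flavipes*, is
$f = (19.3, 13.8, 11.2, 10.0)$ eggs for $k = 1..4$. Two opposed
monotonicities make allocation a real decision problem: per-offspring
fertility $f(k)$ strictly decreases while the all-female per-host yield
$k f(k) = (19.3, 27.6, 33.6, 40.0)$ strictly increases. Packing a host
maximises what one host returns; spreading offspring maximises what a
fixed brood returns. Consequently twelve offspring reared singly are worth
232 eggs in the F2 generation but only 120 (52%) when reared four to a
host — and with both hosts and eggs limited, intermediate allocations win.

Three operations package the resulting phenomena:

* `optimal_allocation()` — exhaustive search for the F2-maximising
  distribution of $N$ offspring over $H$ hosts (all ties reported).
* `find_same_f1_different_f2()` — a pair of allocations with identical
  emerged-offspring counts but different F2 (e.g. 4+2 vs 3+3 over two
  hosts: 67.6 vs 67.2 eggs).
* `find_lower_f1_higher_f2()` — a pair in which the allocation with
  *fewer* F1 offspring has *higher* F2; on the default table this requires
  the higher-F1 allocation to concentrate offspring into large clutches
  (e.g. six 2-clutches, F1 = 12, F2 = 165.6, against four 4-clutches,
  F1 = 16, F2 = 160).

Because $k f(k)$ is strictly increasing, a lower-F1/higher-F2 pair can
never arise between allocations that parasitise the same hosts with the
other allocation dominating host-wise; witnesses necessarily differ in how
many hosts they leave unparasitised (or in sex composition). The search
space treats hosts as exchangeable — F2 is invariant under slot
permutation — so allocations are canonical non-increasing clutch-size
multisets, and "the same number of hosts" is read as the same hosts
*available*, not the same hosts used: females routinely leave part of the
supply unparasitised.

## Sex allocation

Gregarious parasitoids run a female-biased offspring sex ratio, 3:1
female:male for this species; solitary parasitoids approximate 1:1 under
random mating. Deterministic comparisons therefore default to all-female
clutches (the form in which the per-host column $k f(k)$ is tabulated),
while expected-value comparisons (`compare_solitary_gregarious()`,
scenarios, projection) multiply clutch sizes by a female fraction —
0.75 by default, fractional females being the price of expectation
semantics. Over twelve singly parasitised hosts, a solitary 1:1 strategy
expects $12 \times 0.5 \times 19.3 = 115.8$ F2 eggs against the gregarious
$12 \times 0.75 \times 19.3 = 173.7$.

## Scenarios and projection

`expected_scenario()` evaluates a host environment (counts of native and
non-native hosts) under a **clutch frequency distribution**: a probability
mass, per host type, over the empty outcome and clutch compositions. By
linearity of expectation, expected F1 is the native host count times the
expected clutch size; expected F2 multiplies in the per-composition
$n_{\mathrm{F}} f(k)$. Such distributions belong to the data, not the package:
they are estimated clutch frequencies read from CSV/JSON, and percent
contrasts (`percent_change()`) take an explicit baseline argument rather
than hard-coding any published contrast, whose inputs (the empirical
frequency tables) are not distributable here.

`project_generations()` is a deterministic expected-value recursion for
the biocontrol question — how many wasps will be here in 24–28 days
(two 12–14-day generations)? Each generation's total host supply is
divided equally among its females (fractional shares allowed — a density
model, not an individual-based one; no scramble or contest competition is
modelled). Each female allocates clutches over her share via a pluggable
strategy, capped by her egg load; emerged offspring split by the sex
ratio into the next generation's adults. Host supply is exogenous per
generation (no host dynamics); the egg load defaults to unlimited because
the species' fixed complement, while real, is not a packaged constant.
With one founder, twelve hosts per female and singleton clutches the
recursion gives 9 then 81 expected females — closed forms the tests pin.

## Estimation

The statistical procedure is two-step. First, ordinary least squares of
maternal realised fertility on wing length (both treated as normal) gives
the regression line; the fit requires at least three records and two
distinct wing lengths, and degenerate designs fail loudly. Second, each
offspring's *hypothetical* fertility is the fitted line evaluated at its
wing length, clipped at zero — hypothetical because offspring are
measured, not bred. $f(k)$ is the mean over **female** offspring of clutch
size $k$; the companion statistic `mean_females_per_host(k)` is the mean
female count among hosts of that clutch size. Clutch sizes observed with
no females yield flagged `NA` entries, and scoring them errors rather
than extrapolating — the same rule that makes clutches 5–7 representable
but unscorable without a user-supplied extended table.

Confidence intervals follow the two data flavours: the normal-t interval
$\bar x \pm t_{0.975,\,n-1}\, s/\sqrt n$ for continuous summaries and the
exact chi-square (Garwood) interval for Poisson counts, computed on the
total and rescaled to the mean. `exp2_descriptives()` reports group means
and CIs for clutch size and offspring per female; mixed-model inference
on such designs is deliberately out of scope — these are descriptive
summaries feeding external tools.

## The synthetic-data generator

`generate_trial()` emulates the laboratory design: each of 81 females is
offered 12 host eggs in a Petri dish; each host independently receives a
clutch of 0–4 offspring (0 = left unparasitised) drawn from a per-host-type
frequency vector, defaulting to (0.35, 0.20, 0.25, 0.13, 0.07) — about
two-thirds of hosts parasitised, small clutches commonest, matching the
flavour of bench trials at roughly 1.3 offspring per offered host.
Offspring are female with probability 0.75; wing length is
$s_0 - d\,(k-1)$ plus truncated normal noise; latent fertility is
$\mathrm{round}(\max(0, \alpha + \beta w + \varepsilon))$.

The fertility anchors (19.3, 13.8, 11.2, 10.0) are not collinear in $k$,
so no linear-in-$k$ body-size model can hit all four. The default takes
the least-squares-closest affine map, giving achieved generating means
**18.15, 15.10, 12.05, 9.00** eggs (residuals $+1.15, -1.30, -0.85,
+1.00$), recorded in every dataset's truth block; recovery tests compare
against these achieved means, the actual ground truth of the simulation.
Linearity of size in clutch number is itself a modelling minimalism — the
trade-off's direction is established, its functional form is not — and the
body-size parameters ($s_0 = 0.8$ mm, $d = 0.1$ mm, noise sd 0.02 mm;
maternal wings $0.65 \pm 0.05$ mm; fertility noise sd 1.5 eggs) sit on an
arbitrary documented scale: only the composite linear map from clutch size
to expected fertility is identified by the downstream analysis.

Latent offspring fertility exists so that recovery can be scored against
truth; it is deliberately excluded from the observable tables and from
`truth.json` written alongside them, so the estimation stage cannot leak
it. One seed drives three deterministically derived sub-streams (mothers,
hosts, offspring): identical seeds give byte-identical CSVs.

What passing tests on this generator demonstrate — and what they do not:
the pipeline recovers a linear fertility map with independent Gaussian
noise and independent per-host clutch draws. Real trials have
within-mother correlation, self-superparasitism, sequential host
encounter, and measurement error structure none of which is emulated;
recovery there is an empirical question, not a package guarantee.

## Numerical conventions and scales

Internal arithmetic is exact-real throughout; rounding is a reporting
operation. Reported cohort fertilities round to the nearest integer, half
away from zero; relative efficiencies round the *ratio of the rounded*
cohort values to the nearest percent (the round-then-ratio order is fixed
as canonical — at the default table both orders agree on 100/72/58/52).
Floating-point ties in searches use a $10^{-9}$ tolerance. Exhaustive
enumeration is the required algorithm at desk scale and is capped
explicitly at 20 hosts / 40 offspring, failing loudly beyond; the
brute-force comparisons in the test suite run all host/offspring
combinations up to 8, and the statistical recovery checks use 100 seeds of
500 mothers (≈6000 hosts each), sizes at which every clutch class holds
several hundred hosts.

## Known limitations

No superparasitism, larval competition or host feeding: compositions are
fixed at laying. No game theory or dynamic programming over sequential
host encounters — the optimiser answers "which allocation is best", not
"which behavioural rule attains it". The projection has no spatial
structure and no host feedback. And the model's reach is the F2
generation: fitness consequences further on (grand-offspring sex ratios,
mating structure) are outside the accounting.
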