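---
title: "Methods: nomenclature ambiguity scanning, annotation auditing, and the coupled assay model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nomenclature ambiguity scanning, annotation auditing, and the coupled assay model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecaudit)
```

This vignette documents the models and procedures implemented by `ecaudit`,
the choices made where the design was genuinely open, and the limits of what
the test suite demonstrates.

## The problem

Enzyme names are not unique identifiers. The Enzyme Commission (EC) system
classifies *reactions* into a four-level hierarchy
(`class.subclass.sub-subclass.serial`), but the names attached to EC numbers
in nomenclature databases — one accepted name plus alternative names per
entry — can and do collide. When the same name denotes two EC numbers, a
curator transcribing a publication that gives only the name must guess the
number; a wrong guess is then propagated by annotation transfer to
homologous sequences. The best-documented instance involves
"ureidoglycolate hydrolase", shared between EC 3.5.3.19 (amidohydrolase,
releasing 2 NH3 + CO2 from ureidoglycolate) and EC 4.3.2.3 (lyase, releasing
urea), two routes whose distinction matters for nitrogen metabolism and for
ammonia-mediated virulence in several pathogens.

`ecaudit` implements three connected instruments: a database-wide scan for
such shared names, an auditor that flags annotation records matching the
historical misassignment pattern, and a kinetic simulation of the wet-lab
assay that discriminates the two activities.

## Name indexing and the divergence-depth taxonomy

The scan parses an ENZYME-style flat file, indexes the names of every
*active* entry, and reports each canonical name carried by at least two
distinct EC numbers. Design choices:

- **Normalization.** The comparison key is the name lowercased, with
  whitespace runs collapsed, trimmed, and exactly one terminal period
  stripped. This is the minimal rule under which an accepted-name form
  ("Ureidoglycolate hydrolase.") collides with its other-names form
  ("ureidoglycolate hydrolase") while orthographic variants
  ("ureidoglycollate") remain distinct — deliberately conservative, since
  any fuzzier unification would need an unverifiable similarity threshold.
  Whether historical scans of this kind normalized case at all is not
  documentable, so `build_name_index(..., normalize = FALSE)` exposes the
  raw-name convention for sensitivity analysis.
- **Both name roles are indexed.** Accepted (`DE`) and alternative (`AN`)
  names both enter the index, with the role recorded per assignment. The
  motivating collision is precisely an accepted/alternative cross, and
  because roles are reported per row, a reader who wants the
  accepted-names-only convention can recover it from the output.
- **Administrative entries are excluded.** Transferred and deleted entries
  carry administrative description text ("Transferred entry: ..."), not
  names; indexing them would manufacture spurious collisions. The synthetic
  generator plants decoy administrative entries that *reuse* indexed names
  specifically so that any leak of this rule surfaces as a test failure.
- **Divergence depth.** A collision between two complete EC numbers is
  classified by the 1-based index of the first component at which they
  differ. For names with three or more ECs the record takes the *minimum*
  pairwise depth: the most severe reading governs, because the scan's
  purpose is worst-case misclassification risk. Severity classes are a pure
  function of depth: `serial_only` (4), `subclass_level` (2–3),
  `class_level` (1).
- **Counting conventions.** Published counts of this kind are ambiguous
  about whether "differs in the first digit" is a subset of "differs in the
  first three digits". `summarize_scan()` reports per-depth counts plus both
  cumulative columns (`depth_le_3`, `depth_1`), so either convention is
  recoverable; no guess is hard-coded. Headline counts for any particular
  public database release are release-dependent and are not asserted
  anywhere in the package; the same computation is instead validated against
  synthetic databases with exactly known planted collisions and against an
  independent brute-force oracle.

## The audit taxonomy

`audit_records()` checks (protein name, assigned EC) pairs against the index
with three finding kinds, the smallest taxonomy that captures the
documented error mechanisms:

- `ambiguous_name_usage`: the name maps to ≥ 2 ECs — the occasion for error
  (the philological "saut du même au même": identical words inviting a jump
  to the wrong continuation).
- `name_ec_conflict`: the assigned EC matches none of the ECs indexed for
  the name — outright inconsistency with the reference nomenclature.
- `interpolation_risk`: the assigned EC matches one candidate of an
  ambiguous name while another candidate diverges at depth ≤ 3 — the record
  is consistent with the index, yet the assignment may be an interpolation:
  information the cited source never stated, resolved to the wrong branch.
  Depth 4 alternatives are excluded because serial-only siblings are
  essentially the same activity.

Partial assigned ECs (e.g. `3.5.3.-`) match candidates by component prefix
and a prefix match counts as consistent — conservative, fewer false alarms.
Name matching is exact after normalization; there is no fuzzy matching.
Records with unparseable assigned ECs are skipped with a diagnostic rather
than flagged, so garbage input cannot masquerade as a biological finding.

## The coupled assay model

The simulation reproduces the logic of the continuous spectrophotometric
assay. Species are concentrations in mM in a fixed volume; time in minutes.
Reactions:

| reaction | rate law |
|---|---|
| ureidoglycolate + H2O → 2 NH3 + CO2 + glyoxylate (amidohydrolase) | Michaelis–Menten on ureidoglycolate |
| ureidoglycolate → urea + glyoxylate (lyase) | Michaelis–Menten on ureidoglycolate |
| ureidoglycolate → urea + glyoxylate (spontaneous decay) | first order, `k_decay` |
| urea + H2O → 2 NH3 + CO2 (urease) | Michaelis–Menten on urea, active from `urease_time` |
| NH3 + α-ketoglutarate + NADH → glutamate + NAD⁺ (GDH) | Vmax × product of the three substrate saturation terms |

The readout is NADH consumed (the A340 proxy): GDH captures one NADH per
ammonia, so the readout trace is the continuous ammonia signal. Cumulative
`nh3_released` and `urea_released` are integrated alongside as bookkeeping
states so endpoint ratios include ammonia already fixed into glutamate.

Assumptions and simplifications:

- The mechanistic intermediates of the hydrolytic route (carbamate,
  hydroxyglycine) are lumped into one step, and glyoxylate hydration is
  ignored: neither moves nitrogen nor the readout.
- The pre-reaction that generates ureidoglycolate from allantoate is not
  simulated; ureidoglycolate is an initial condition (0.085 mM by default,
  with 0.35 mM NADH and 2.5 mM α-ketoglutarate, matching the reference
  mixture in which the substrate is produced stoichiometrically from
  allantoate before the enzyme under test is added).
- Metal dependence is out of scope: an enzyme is either present or absent.
- Nitrogen is conserved as 2·UG + 2·urea + NH3 + glutamate; carbon as
  3·UG + urea + CO2 + 2·glyoxylate + 5·αKG + 5·glutamate. Every reaction
  row conserves both, so mass-balance closure is a pure test of the
  integration, independent of rate parameters.

### Parameters

No rate constants for these enzymes are established well enough to adopt,
so defaults are order-of-magnitude choices made once: Km 0.05 mM and
Vmax 0.05 mM/min for the enzyme under test (the 0.085 mM substrate is
consumed within minutes, matching the timescale of a practical continuous
assay); urease (Vmax 2 mM/min, Km 0.2 mM) and GDH (Vmax 5 mM/min) fast and
non-limiting, as coupling enzymes are used in large excess. The
stoichiometric endpoints that constitute the package's quantitative claims
are parameter-independent by construction, which the test suite verifies by
randomizing Vmax and Km over two orders of magnitude.

The spontaneous decay of ureidoglycolate is real but unquantified
("moderately stable"); the default `k_decay = 0.001`/min (half-life ≈ 11.5 h)
is slow relative to enzymatic turnover. Two consequences are treated
explicitly:

- **Route endpoint measurements disable the decay** (`k_decay = 0`). The
  decay is a *competing route* that diverts a small fraction of substrate
  through urea; the stoichiometry of an enzymatic route is a property of
  that route, not of the mixture, so the route is simulated in isolation.
- Only **order relations** are asserted about decay kinetics: with urease
  present, decay-only ammonia has a strictly later half-rise time than the
  enzymatic lyase signal whenever the decay constant is below the lyase's
  initial turnover rate — the property that explains delayed ammonia
  production in deletion strains lacking the lyase.

### Classification

`classify_activity()` compares the ammonia released by the end of a run
without urease against a matched run with urease, as a fraction r of the
*initial* ureidoglycolate: r_without > 1.5 → amidohydrolase;
r_without ≤ 0.1 and r_with > 1.5 → lyase; both ≤ 0.1 → none; anything in
between raises an indeterminate error rather than guessing. The denominator
is the initial rather than consumed substrate so that a slow-decay-only
scenario — where consumption within the horizon is negligible —
classifies as `none` instead of erroring or misclassifying; the two
denominators coincide whenever consumption is complete.

### Numerics

Integration uses `deSolve::vode` (implicit BDF, stiff-capable) with
`rtol = 1e-10`, `atol = 1e-12` and a step cap of 1 min. The step cap and
the choice of a BDF method are robustness measures: the network becomes
exactly quiescent after substrate exhaustion, a regime where adaptive
dense-output interpolation in some multistep codes can fail. Mid-run urease
addition is handled by splitting the integration at the event and
restarting, never by a discontinuous rate inside one solver call. Michaelis–
Menten terms are evaluated on states clamped at zero inside the derivative
(round-off can push states infinitesimally negative); the returned curve is
clamped likewise, and any excursion beyond 1e-6 relative to the largest
pool aborts with an instruction to tighten tolerances. The readout is
reported through a running maximum, removing integrator jitter from an
analytically non-decreasing signal.

`endpoint_stoichiometry()` refuses to report ratios unless ≥ 99.9% of the
substrate has been consumed, because partial-consumption ratios are
kinetically biased; the error suggests extending the horizon.

## The synthetic generators

`generate_enzyme_dat()` emulates an ENZYME-style release with exact ground
truth: background entries with names unique by construction (an indexed
"substrateNNNN ...ase" grammar, so accidental collisions are impossible),
planted collisions whose EC pairs are constructed to first differ at
exactly the requested depth, administrative decoys, and shuffled entry
order. EC components are sampled within the real grammar (class 1–7,
others 1–99). `generate_annotation_records()` plants name/EC conflicts and
interpolation-pattern records at requested fractions, drawing clean records
only from unambiguous names so ground-truth labels are exact.

What the generators do **not** emulate: the size, name-length statistics,
linguistic structure, or collision-depth distribution of any real release;
multi-line wrapped records; comment blocks; cross-reference lines beyond
pass-through. Passing tests therefore demonstrate the correctness of the
computations on structurally faithful inputs, not the reproduction of any
particular release's counts — those depend on the release archived at scan
time and are explicitly not asserted.

Test problem sizes: the oracle-equivalence suite runs 100 seeded databases
of 20–500 entries against an independent quadratic brute-force scan;
kinetic-invariance checks run 10 randomized parameter draws over a 600 min
horizon at 0.5 min reporting resolution. These sizes were chosen as the
smallest that exercise every code path and depth class while keeping the
suite quick to run routinely.

## Known limitations

- The scan is exact-match after normalization: misspelled or reworded
  duplicate names are invisible to it.
- The audit needs a reference index; it can flag inconsistency with the
  reference, not decide which side is wrong.
- Partial-EC prefix matching treats e.g. `3.5.3.-` as consistent with any
  `3.5.3.x` candidate; a curator may still consider such a record
  underspecified.
- The assay model has no observation noise, photobleaching, enzyme
  inactivation, or metal-dependence effects; it is a stoichiometric/kinetic
  skeleton for reasoning about assay design, not a fitting model for real
  absorbance traces. Fitting rate constants to published progress-curve
  figures is deliberately out of scope.
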