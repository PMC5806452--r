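---
title: "Quantifying implementation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying implementation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impquant)
```

## The model

`impquant` operationalizes a quantitative process evaluation for
multi-component interventions delivered in stepped-wedge cluster
randomized trials. The model separates *delivery* — what the
organization and its deliverers provided — from *receipt* — what each
participant took up — and chains them multiplicatively:

- Every raw response is rescored to a 0–100 scale before aggregation:
  on five-category Likert items the two most positive categories score
  100, the middle 50, the two most negative 0; four-category
  success-criterion ratings score not/partly/completely/more-in-depth as
  0/50/100/100 (the in-depth category is recorded but earns no bonus);
  the 0–10 self-rated performance scale is banded 0–4/5–7/8–10 to
  0/50/100 and the 0–10 physical-intensity scale 0–3/4–5/6–7/8–10 to
  0/50/75/100.
- Per held session, content `C` is the mean of the scored criteria (for
  intensity-rated training sessions the scored intensity joins the mean
  as one additional element of equal weight — the protocol says
  intensity is *considered* with the criteria but assigns no weight, so
  equal weight is the minimal assumption and a deliberate modelling
  choice), quality `Q` is the equal-weight mean of the understanding
  index, contribution index and performance score, and fidelity is
  `F = (C + Q)/2`.
- Dose `D` is sessions held over sessions planned. Organizational
  implementation is `(D + F)/2`; "fidelity of intended sessions" is
  `F × D`.
- Participation weights presence by duration over the planned total
  (27 h in the packaged protocol); team-mode sessions receive the
  team's combined representation/continuity score, broadcast to every
  member.
- Per session and participant, exposure is `E = F × P` and
  implementation `I = E × R`, with responsiveness `R` the mean of the
  satisfaction index, support index and attendance-weighted motivation.
  Totals sum over all planned sessions; a session the organization
  cancelled contributes zero presence, hence zero exposure, no matter
  how faithful the other sessions were. Any factor equal to zero zeroes
  the implementation score.

The key modelling assumptions are (i) equal weighting inside every mean
(no item, criterion or sub-index is privileged), (ii) responsiveness
measured once at the end of the intervention and applied as a constant
per participant across sessions, and (iii) the team-level combined
score standing in for individual presence at team-mode sessions — the
intended "contamination" of a participatory component within a team.

## Parameters that matter

| Parameter | Units / domain | Default | Why |
|---|---|---|---|
| `total_hours` | hours | 27 | sum of planned per-participant durations; the participation denominator |
| representation schedule | team size → count | <5→2, 5–9→3, 10–14→4, 15–19→5, ≥20→6 | the required-representative quota for team-mode scoring |
| `max_missed` (continuity) | sessions | 0 | strict reading of "the same representatives in all sessions"; raise to tolerate absences |
| attendance cap | — | capped at 1 | scores live on 0–100; attendance beyond the quota cannot exceed 100% |
| missing-logbook policy | — | missing, not zero | absence of measurement is not zero fidelity; held-but-unscored sessions count in dose only |
| percent rendering | — | half away from zero | 0.875 → 88%, 713/753 → 95%; applied only at the reporting boundary |

Scores are carried at full precision as fractions (or 0–100 scores)
internally; rounding to whole percent happens only when formatting.
This matters: the worked chain 0.65 × 3/27 = 0.072 only reproduces at
full-precision carry.

## Numerical and edge-case choices

- Missing single items inside an index use the available-item mean; an
  index with no answered items is missing, and missingness propagates
  without raising.
- Participants without a questionnaire have missing responsiveness and
  implementation but keep participation and exposure — stratified
  summaries therefore report different `n` per measure, and the
  implementation mean describes the (attendance-selected) responder
  population.
- Individual-level fidelity is the duration-and-presence-weighted mean
  of session fidelity over *attended* sessions. This convention makes
  fidelity, participation and exposure cohere exactly
  (exposure = mean fidelity × participation when fidelity is constant)
  and leaves fidelity undefined for participants who attended nothing.
- Reported SDs are sample SDs (n−1), the convention for trial summary
  tables; a single-observation stratum reports SD 0, an empty one NA.
- Zero-variance item matrices make Cronbach's alpha undefined (error),
  and one-way ANOVA refuses single-group or saturated designs.
- Dose is undefined for zero intended sessions and a delivered count
  above the intended count is a consistency error, not a score above 1.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults encode a four-workplace stepped-wedge trial:
594 participants in 58 teams, four steps of 126/146/158/164
participants, and 753 scheduled sessions of the packaged 19-session /
27-hour protocol. The paper-style session budget is reproduced by a
delivery-unit decomposition the trial reports only in aggregate, so the
unit structure is a modelling choice: 16 kick-off assemblies (one per
workplace-step cell), 39 ergonomics working groups of one or two teams
holding 4 team-mode sessions each (16 + 156 = 172), 42 training groups
with 12 weekly sessions of which three groups merge one week
(504 − 3 = 501), and 40 workshop groups holding 2 workshops (80).
Since the protocol only fixes the component totals (9 h over five
ergonomics sessions), the kick-off is set to 1 h and the four team-mode
sessions to 2 h each.

Behaviour defaults are chosen once to mirror the trial's published
margins: per-component cancellation probabilities (0.006/0.074/0.025)
reproducing ~95% dose; content/quality propensities
(0.95–0.96/0.86/0.92–0.93) giving held-session fidelity near 91;
attendance probabilities 0.60/0.38/0.48 for kick-off/training/workshop
sessions and representative attendance 0.87, which combine to overall
participation near 0.50; satisfaction/support/motivation propensities
0.83/0.93/0.92 giving responsiveness near 89.

Two generator mechanisms deserve note. Category ratings are drawn by
thresholding a latent uniform against the configured propensity
(mixing the two adjacent score levels), so the *expected* scored value
equals the propensity exactly — no distributional assumption beyond
that is made, because the scales cannot support one. Attendance uses a
logit-normal per-participant propensity (SD 1.3 on the logit scale),
and questionnaire response is tied to presence at the final workshop
(probability 0.92 if present, 0.08 if not); together these reproduce
both the ≈50% response rate and the strong participation gap between
responders and non-responders without a separately tuned correlation
parameter. Each output table draws from its own seed-derived stream,
so regenerating one table never perturbs the others.

The generator does *not* emulate: real teams' correlated attendance
(car-pooling, shift patterns), deliverer learning over steps (a step
drift parameter exists but defaults to zero), item-level response
styles, partial session attendance, or any outcome (e.g. low-back
pain) downstream of implementation. Passing tests on generated data
therefore demonstrate the *arithmetic and statistical coherence* of the
pipeline under known truth, not the behaviour of any real trial.

## Verification strategy and problem sizes

The unit tests work on a hand-built 10-hour miniature trial (two teams,
ten participants, twelve sessions) whose every score is computable by
hand, plus property-style loops: chain inequality
`I_all ≤ E_all ≤ participation`, zero propagation, permutation
invariance of indexes, continuity bounded by the best single-session
participation, and exact factorization of exposure under constant
fidelity. Full-scale checks run the complete n = 594 generator — shape
reproduction, clean validation, determinism by seed, responder
selection, parameter recovery over 3 replicates, and an injected
10-point workplace attendance effect detected by ANOVA. The calibrated
product-structure check uses 8 replicates of the full trial, comparing
the mean implementation of responders with fidelity × participation ×
responsiveness at the responder level within three Monte-Carlo
standard errors; reliability checks compare Cronbach's alpha against
closed forms and a Spearman–Brown prediction at n = 4000 simulated
respondents.

## Known limitations

- The continuity score's strict "attended everything" reading is one of
  several defensible formalizations; it is isolated behind
  `team_continuity(max_missed =)` for substitution.
- Component-level satisfaction includes the three overall items next to
  the component-specific one; whether overall items belong there is a
  judgment call, kept because a single item is a fragile index.
- "Fidelity of intended sessions" as `F × D` does not decompose the
  per-component discount any further; it inherits whatever
  heterogeneity the held-session fidelity mean hides.
- Post hoc multiple comparisons, repeated-measures designs across
  components, intraclass correlation of logbooks against observations,
  and index derivation by PCA are out of scope; the comparison tables
  expose per-group n/mean/SD so external tools can take over.
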