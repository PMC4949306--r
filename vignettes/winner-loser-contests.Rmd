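---
title: "Winner-loser contests and the evolution of aggression thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Winner-loser contests and the evolution of aggression thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wlgame)
```

## The model

Animals meeting for the first time settle their dominance relations through
repeated aggressive contests. Two empirical regularities shape this process:
winners of earlier fights tend to win again (the *winner effect*) and losers
tend to keep losing (the *loser effect*). `wlgame` models both through a
single score, the *resource holding potential* (RHP): every individual
starts at the same `rhp_initial`, and each interaction multiplies the score.
Winning an escalated fight multiplies RHP by $1+V_1$ and losing by $1-C_1$;
a fighter facing a retreating opponent gains $1+V_2$ while the retreater
takes $1-C_2$; if both retreat (a double kowtow, only possible in the very
first round) both take $1-C_2$. When both individuals escalate, the
probability that $x$ beats $y$ is its RHP share,
$\mathrm{RHP}_x/(\mathrm{RHP}_x+\mathrm{RHP}_y)$.

The strategic element is an *aggression threshold* $\theta$: an individual
fights exactly when its RHP ratio to the opponent is at least $\theta$
(inclusive, so $\theta = 1$ fights from the even start, and $\theta > 1$
concedes immediately). Throughout the exact analysis we use the default
preset $V_1=V_2=V$, $C_1=C$, $C_2=0$: beating a fighter and beating a
retreater pay alike, losing a fight is an injury, retreating is free. Both
assumptions matter — they are what makes the analysis below exact.

Two payoff currencies are supported at the horizon $T$:

* **log-RHP** ($E[\ln \mathrm{RHP}_T]$): suitable when resources are
  plentiful and absolute fighting ability converts into fitness. The
  logarithm makes every win (loss) worth the same increment regardless of
  the current score, exactly as in matrix games of the Hawk–Dove family.
* **share** ($E[\ln \mathrm{RHP}_{x,T}/(\ln \mathrm{RHP}_{x,T} +
  \ln \mathrm{RHP}_{y,T})]$): the expected fraction of a *limited* resource
  divided in proportion to log RHP (a reproductive-skew reading). Shares of
  the two players sum to one path by path, so share matrices are
  complementary with an exactly 0.5 diagonal.

## From thresholds to concession classes

Because updates are multiplicative and both players start even, the RHP
ratio after $a$ wins and $b$ losses is $((1+V)/(1-C))^{a-b}$. A threshold
$\theta$ therefore acts through a single number, the critical deficit

$$d = \frac{-\ln\theta}{\ln(1+V)-\ln(1-C)},$$

and an individual retreats the first time its wins-minus-losses difference
reaches $-k$, where $k = \lfloor d \rfloor + 1$ is the integer *concession
class*. All thresholds in the interval
$[((1-C)/(1+V))^{k}, ((1-C)/(1+V))^{k-1})$ share a class and hence a payoff;
`theta_rep()` labels the class by the interval midpoint. The boundary
convention follows from applying the inclusive fight rule literally: a
threshold exactly on an endpoint still fights there, which also places
$\theta = 1$ in class 1. (The alternative convention $k = \lceil d\rceil$
differs only on the measure-zero set of integer $d$; every representative
strategy sits strictly inside its interval, where both agree.) Numerically,
`class_from_theta()` adds a $10^{-9}$ fuzz before flooring so that
representative thresholds round-trip to their own class despite
floating-point error; only thresholds within $10^{-9}$ of an endpoint can
be affected.

```{r classes}
class_from_theta(0.61, V = 0.1, C = 0.1)
round(theta_rep(1:8, 0.1, 0.1), 2)
```

## Exact payoffs by dynamic programming

While both players fight, the difference $d_t = a_t - b_t$ performs a random
walk with state-dependent step probability `win_prob_from_diff(d)`,
absorbing at $-k_x$ (x concedes) and $+k_y$ (y concedes). After absorption
the loser's score freezes (retreating is free) while the winner gains
$1+V$ in each remaining round. `expected_payoff()` runs a forward
probability pass over $(t, d)$ — cost $O(T(k_x+k_y))$ instead of the $2^T$
sum over outcome sequences — and is computed entirely in log space, so
large horizons cannot overflow. `expected_payoff_bruteforce()` is the
deliberately independent oracle: it enumerates the full outcome tree (up to
$2^T$ paths, refused above $T = 14$) and must agree within $10^{-10}$; the
test suite enforces this on random parameter fixtures, and a Monte-Carlo
simulation of the raw micro-rules provides a third, stochastic route.

Degenerate inputs are rejected rather than patched: $C_1 = 1$ or $C_2 = 1$
annihilates RHP and makes the log payoff undefined; $V = C = 0$ leaves the
threshold mapping without meaning; share payoffs raise an error if any
reachable terminal log RHP is non-positive (with the defaults,
`rhp_initial = 10`, this cannot happen at $T \le 200$).

The contest *stopping time* — the round of the last mutual fight — is the
first-passage time of the same walk; `stopping_distribution()` returns its
exact mass plus the probability that nobody has conceded by $T$, and
`stopping_support()` gives the closed-form support: a point mass at round 1
when $k_x = k_y = 1$; the rounds $\min(k_x,k_y) + 2n$ when the class sum is
even; and, for mixed parities, the rounds below $\max(k_x,k_y)$ with the
parity of the smaller class together with every round from the larger class
upwards.

## The ESS of the two-player game

`contest_game()` assembles the payoff matrix over classes $1..k_{\max}$
(default 8 — an arbitrary cut-off that only needs to contain the ESS
strictly inside the grid) and applies the *diagonal rule*: a pure strategy
is evolutionarily stable when its diagonal entry strictly exceeds every
other entry of its column. Exact payoff ties (within a $10^{-9}$ tolerance
that separates genuine ties from round-off) fall through to the
second-order condition $E[\theta_x,\theta_y] > E[\theta_y,\theta_y]$
against each tying invader. Mixed ESSs are not searched: on these grids the
first condition resolves every case except the fully tied columns of the
$V=0$ game, where the second condition promotes immediate retreat. When
$V = 0$ the never-fight class 0 is added to the grid, since fighting can
then only hurt.

```{r ess}
g <- contest_game(V = 0.1, C = 0.1, T = 20)
g
coef(g)
contest_game(V = 0.1, C = 0.1, T = 20, payoff = "share")$ess
```

Under the plentiful-resource payoff the stable class at $V = C = 0.1$,
$T = 20$ is $k = 3$ (thresholds $[0.55, 0.67)$); under the share payoff it
is the more aggressive $k = 5$ — with scarce resources it pays to damage
the opponent because the payoff is relative. `ess_sweep()` repeats this
over grids of $V$ and $C$; raising $V$ at fixed $C$ lowers the stable
threshold (longer fighting), raising $C$ does the opposite.

The scaling law `scale_strategy()` ($\theta' = \theta^\alpha$ when $V, C$
become $\alpha V, \alpha C$) is a first-order approximation in $V + C$;
`scaling_consistency()` reports the exact critical deficits on both sides
and flags when the approximation actually changes the class. A warning is
issued beyond $V + C = 0.3$, where the linearisation degrades.

## The N-player evolutionary simulation

For groups larger than two the exact analysis is intractable, so
`run_evolution()` estimates the stable threshold by simulation. Each
generation, many groups of $N$ individuals are formed by sampling
strategies i.i.d. from the current frequency vector over the grid
$\Theta = (0.1, 0.2, \ldots, 1.0)$; within each group a uniformly random
pair interacts per round for `contests` rounds; each individual then
credits its final $\ln \mathrm{RHP}$ to its strategy's accumulator $H$, and
the next generation's frequencies are $p_k = H_k / \sum_k H_k$. There is no
mutation, so a strategy that loses all mass is gone for good, and a
monomorphic population is absorbing. The proportional update needs
non-negative fitness; credited payoffs are clamped at a configurable floor
(default 0, with a warning). With the defaults the clamp is essentially
never needed at $N = 2$, but at $N = 4$ with 200 contests a rare individual
drawn into most of its group's rounds can dip below $\ln \mathrm{RHP} = 0$,
so occasional clamp warnings there are expected behaviour.

**The contest horizon is part of the game.** The stable threshold depends
on how long payoffs accumulate: once an opponent concedes, the winner keeps
harvesting $1+V$ every remaining round, so longer horizons reward
aggression. With $V = C = 0.1$ the exact grid ESS is $\theta = 0.6$ at a
20-round horizon but $\theta = 0.3$ at a 200-round horizon — and the
simulation, run at either horizon, recovers the matching exact answer
(this cross-check is a test). Consequently, when the simulation is used to
*validate* the two-player analysis the contest count must equal the
analysis horizon $T$; the package's $N = 2$ validation runs and the
acceptance script therefore use `contests = 20` against the $T = 20$
analysis, while group-size comparisons at $N = 4$ keep the algorithm's
200-contest generations (which at $V = C = 0.1$ also settle on
$\theta = 0.6$).

Scale defaults are the package's own choices: `scale = "desk"` uses 500
groups and 300 generations with early stopping once one strategy has held
at least $1 - 10^{-3}$ of the mass for 25 consecutive generations —
selection near the optimum is weak (adjacent classes differ by under 1% in
payoff), so desk-scale runs concentrate but may not fixate; `scale =
"paper"` uses 10,000 groups and 10,000 generations with early stopping off.
The declared ESS is the modal strategy when the final distribution is
concentrated (modal frequency at least one half) and the frequency-weighted
mean otherwise, which is the robust readout at desk scale.

```{r evolve}
cfg <- evolution_config(N = 2, params = game_params(V = 0.1, C = 0.1),
                        contests = 20, n_groups = 500, n_generations = 300)
evo <- run_evolution(cfg, seed = 1)
evo
```

## What the simulation does and does not emulate

The generator reproduces the model's idealisations, not field data:
identical initial RHP (no intrinsic size or age differences), perfect
mutual knowledge of scores, multiplicative score updates of constant
proportion, uniform random pairing without spatial or social structure, one
fixed threshold per individual per lifetime, and selection acting only
through the current generation's accumulated log RHP (no carry-over, no
elitism, no mutation). Passing tests therefore show that the implementation
is faithful to this model — not that real hierarchies form this way.
Deviations to expect in real data include assessment error (which blurs the
sharp threshold rule), intrinsic asymmetries (which dominate early rounds),
and diminishing returns on repeated wins (which the constant multiplier
overstates at long horizons; realistic uses should keep $V$, $C$ and the
horizon moderate).

## Numerical choices, in one place

* RHP is carried in log space everywhere; ratio space appears only in user
  I/O.
* Class mapping: `floor(d + 1e-9) + 1`; ESS comparisons: strict beyond
  `1e-9`, ties fall to condition 2.
* Brute-force oracle refuses $T > 14$; the DP has no such limit.
* Share payoffs for equal classes return exactly 0.5 by symmetry rather
  than through summation.
* The Monte-Carlo engine consumes exactly three uniforms per group-round
  regardless of outcome, so seeded trajectories are bit-reproducible.
* Fitness floor 0 with a warning; total non-positive credited fitness is a
  hard error.

## Known limitations

* The exact machinery requires the default preset ($V_1=V_2$, $C_2=0$);
  generalised presets are simulated, not solved.
* No mixed-strategy ESS search and no closed-form $T \to \infty$ limits.
* Desk-scale evolutionary runs carry residual drift: with weak selection
  the mode can land one grid step away from the exact class on unlucky
  seeds; the paper-scale settings remove this at real cost in time.
* The share payoff is undefined when a terminal log RHP can reach zero;
  choose `rhp_initial` accordingly.
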