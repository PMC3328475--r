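"""Exhaustive exact-rational oracle for the two-sided 2x2 Fisher test.

Enumerates every 2x2 table [[a, b], [c, d]] of non-negative counts whose
row and column margins are all <= M (first argument, default 30), computes
the two-sided minimum-likelihood p-value with exact Fraction arithmetic
(sum of hypergeometric probabilities <= that of the observed table, exact
comparison), and writes one line per table to the output file (second
argument): a b c d p, tab-separated, p rendered as a double.
"""
import sys
from fractions import Fraction
from math import comb

M = int(sys.argv[1]) if len(sys.argv) > 1 else 30
out_path = sys.argv[2] if len(sys.argv) > 2 else "/dev/stdout"

with open(out_path, "w") as out:
    for r1 in range(M + 1):
        for r2 in range(M + 1):
            n = r1 + r2
            for c1 in range(min(n, M) + 1):
                c2 = n - c1
                if c2 > M:
                    continue
                denom = comb(n, c1) if n else 1
                klo, khi = max(0, c1 - r2), min(c1, r1)
                ks = list(range(klo, khi + 1))
                probs = [Fraction(comb(r1, k) * comb(r2, c1 - k), denom)
                         for k in ks]
                # p(k) = sum of probabilities <= prob(k), ties sharing the
                # whole tied mass: prefix sums over the sorted values,
                # assigned after each tie group
                order = sorted(range(len(probs)), key=probs.__getitem__)
                pval = [Fraction(0)] * len(probs)
                acc = Fraction(0)
                i = 0
                while i < len(order):
                    j = i
                    while (j + 1 < len(order)
                           and probs[order[j + 1]] == probs[order[i]]):
                        j += 1
                    group = order[i:j + 1]
                    acc += sum(probs[g] for g in group)
                    for g in group:
                        pval[g] = acc
                    i = j + 1
                for k, p in zip(ks, pval):
                    a, b = k, r1 - k
                    c, d = c1 - k, r2 - (c1 - k)
                    out.write(f"{a}\t{b}\t{c}\t{d}\t{float(p):.17g}\n")
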