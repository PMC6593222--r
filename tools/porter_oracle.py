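"""Independent transcription of the classic Porter (1980) suffix-stripping
algorithm, in the index-based style of the original C implementation.

Used only at development time to freeze word -> stem pairs into
tests/testthat/fixtures/porter-reference.tsv; the R package carries its own
implementation written against the published rule tables.

Conventions, matching the reference implementations:
  * operates on lowercase words
  * strings of length <= 2 are returned unchanged
  * within a rule block, the longest matching suffix is selected and only
    that rule's condition is consulted
"""

VOWELS = "aeiou"


class PorterStemmer:
    def __init__(self):
        self.b = ""
        self.k = 0  # index of last char of the current word

    def cons(self, i):
        ch = self.b[i]
        if ch in VOWELS:
            return False
        if ch == "y":
            return True if i == 0 else not self.cons(i - 1)
        return True

    def m(self, j):
        """Number of VC sequences in b[0..j]."""
        n = 0
        i = 0
        while True:
            if i > j:
                return n
            if not self.cons(i):
                break
            i += 1
        i += 1
        while True:
            while True:
                if i > j:
                    return n
                if self.cons(i):
                    break
                i += 1
            i += 1
            n += 1
            while True:
                if i > j:
                    return n
                if not self.cons(i):
                    break
                i += 1
            i += 1

    def vowel_in_stem(self, j):
        return any(not self.cons(i) for i in range(j + 1))

    def doublec(self, j):
        if j < 1:
            return False
        if self.b[j] != self.b[j - 1]:
            return False
        return self.cons(j)

    def cvc(self, i):
        if i < 2 or not self.cons(i) or self.cons(i - 1) or not self.cons(i - 2):
            return False
        return self.b[i] not in "wxy"

    def ends(self, s):
        length = len(s)
        if length > self.k + 1:
            return False
        if self.b[self.k - length + 1 : self.k + 1] != s:
            return False
        self.j = self.k - length
        return True

    def setto(self, s):
        self.b = self.b[: self.j + 1] + s
        self.k = len(self.b) - 1

    def r(self, s):
        if self.m(self.j) > 0:
            self.setto(s)

    def step1ab(self):
        if self.b[self.k] == "s":
            if self.ends("sses"):
                self.k -= 2
            elif self.ends("ies"):
                self.setto("i")
            elif self.b[self.k - 1] != "s":
                self.k -= 1
        if self.ends("eed"):
            if self.m(self.j) > 0:
                self.k -= 1
        elif (self.ends("ed") or self.ends("ing")) and self.vowel_in_stem(self.j):
            self.k = self.j
            self.b = self.b[: self.k + 1]
            if self.ends("at"):
                self.setto("ate")
            elif self.ends("bl"):
                self.setto("ble")
            elif self.ends("iz"):
                self.setto("ize")
            elif self.doublec(self.k):
                if self.b[self.k] not in "lsz":
                    self.k -= 1
                    self.b = self.b[: self.k + 1]
            elif self.m(self.k) == 1 and self.cvc(self.k):
                self.j = self.k
                self.setto("e")
        self.b = self.b[: self.k + 1]

    def step1c(self):
        if self.ends("y") and self.vowel_in_stem(self.j):
            self.b = self.b[: self.k] + "i"

    def _rule_block(self, rules, min_m):
        """Apply the longest matching suffix rule from `rules`
        ((suffix, replacement) pairs); condition m(stem) > min_m - 1."""
        best = None
        for suf, rep in rules:
            if self.ends(suf):
                if best is None or len(suf) > len(best[0]):
                    best = (suf, rep)
        if best is not None:
            self.ends(best[0])  # re-establish self.j
            if self.m(self.j) >= min_m:
                self.setto(best[1])

    STEP2 = [
        ("ational", "ate"), ("tional", "tion"), ("enci", "ence"),
        ("anci", "ance"), ("izer", "ize"), ("abli", "able"), ("alli", "al"),
        ("entli", "ent"), ("eli", "e"), ("ousli", "ous"), ("ization", "ize"),
        ("ation", "ate"), ("ator", "ate"), ("alism", "al"),
        ("iveness", "ive"), ("fulness", "ful"), ("ousness", "ous"),
        ("aliti", "al"), ("iviti", "ive"), ("biliti", "ble"),
    ]
    STEP3 = [
        ("icate", "ic"), ("ative", ""), ("alize", "al"), ("iciti", "ic"),
        ("ical", "ic"), ("ful", ""), ("ness", ""),
    ]
    STEP4 = [
        "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
        "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize",
    ]

    def step2(self):
        self._rule_block(self.STEP2, 1)

    def step3(self):
        self._rule_block(self.STEP3, 1)

    def step4(self):
        best = None
        for suf in self.STEP4:
            if self.ends(suf):
                if best is None or len(suf) > len(best):
                    best = suf
        if best is None:
            return
        self.ends(best)
        if best == "ion" and not (self.j >= 0 and self.b[self.j] in "st"):
            return
        if self.m(self.j) > 1:
            self.k = self.j
            self.b = self.b[: self.k + 1]

    def step5(self):
        self.j = self.k
        if self.b[self.k] == "e":
            # trailing e never completes a VC pair, so m(stem) == m(word)
            stem_m = self.m(self.k - 1) if self.k >= 1 else 0
            if stem_m > 1 or (stem_m == 1 and not self.cvc(self.k - 1)):
                self.k -= 1
                self.b = self.b[: self.k + 1]
        if self.b[self.k] == "l" and self.doublec(self.k) and self.m(self.k) > 1:
            self.k -= 1
            self.b = self.b[: self.k + 1]

    def stem(self, word):
        word = word.lower()
        if len(word) <= 2:
            return word
        self.b = word
        self.k = len(word) - 1
        self.step1ab()
        self.step1c()
        self.step2()
        self.step3()
        self.step4()
        self.step5()
        return self.b


if __name__ == "__main__":
    import sys

    p = PorterStemmer()
    for line in sys.stdin:
        w = line.strip()
        if w:
            print(f"{w}\t{p.stem(w)}")
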