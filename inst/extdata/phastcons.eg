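;; Rate-multiplier phylo-HMM: numNonterms emitting nonterminals sharing one
;; substitution model, each scaled by its own rate multiplier r_k.  A
;; transition between nonterminals happens with probability
;; leaveProb/(numNonterms - 1) and self-transitions with stayProb.

(alphabet
 (name DNA)
 (token (a c g t))
 (complement (t g c a))
 (wildcard * n x))

(grammar
 (name phastcons)

 (&define numNonterms 3)
 (&define SEED 0.001)
 (&define u 1.0)

 ;; one rate multiplier per nonterminal
 (&foreach-integer nonterminal (1 numNonterms)
  (rate ((&cat r_ nonterminal) SEED)))

 ;; the shared underlying substitution model, one rate entry per ordered
 ;; token pair
 (&foreach-token tok1
  (&foreach-token tok2
   (&if (&eq tok1 tok2)
    () ;; if tok1 == tok2, expand to an empty list (ignored by parser)
    (rate (&cat Q_ tok1 _ tok2) u))))

 ;; one chain per nonterminal: the shared model scaled by r_nonterminal
 (&foreach-integer nonterminal (1 numNonterms)
  (chain
   (terminal (&cat chain_ nonterminal))
   (&foreach-token tok1
    (&foreach-token tok2
     (&if (&eq tok1 tok2)
      ()
      (mutate (from (tok1)) (to (tok2))
       (rate (&cat Q_ tok1 _ tok2) (&cat r_ nonterminal))))))))

 (pgroup (stayProb 0.9) (leaveProb 0.1))

 (&foreach-integer nonterm1 (1 numNonterms)
  ;; Each nonterminal has a transition from start
  (transform (from (start)) (to (nonterm1)) (prob (&/1 numNonterms)))
  ;; Each nonterminal can transition to end - we assign this prob 1
  ;; since the alignment length directs when this transition occurs
  (transform (from (nonterm1)) (to ()) (prob 1))
  (&foreach-integer nonterm2 (1 numNonterms)
   (&if (&eq nonterm1 nonterm2)
    ;; If nonterm1 == nonterm2, this is a self-transition
    (transform (from (nonterm1)) (to (nonterm2)) (prob stayProb))
    ;; Otherwise, an inter-nonterminal transition with probability
    ;; leaveProb/(numNonterms - 1)
    (transform (from (nonterm1)) (to (nonterm2))
     (prob (&/leaveProb (&- numNonterms 1)))))))

 ;; Lastly, associate each nonterminal with its chain
 (&foreach-integer nonterminal (1 numNonterms)
  (transform (from (nonterminal))
             (to ((&cat chain_ nonterminal) (&cat nonterminal *))))
  (transform (from ((&cat nonterminal *))) (to (nonterminal))))

 ;; annotation directives: label each column with its nonterminal
 (&foreach-integer k (1 numNonterms)
  (annotate (nonterminal k) (row RATE) (label k))))
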