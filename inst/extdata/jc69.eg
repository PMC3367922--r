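;; Jukes-Cantor DNA chain written with nested alphabet-token loops, wrapped
;; in a trivial one-state grammar (start -> emit; emit emits one column via
;; the JC pseudoterminal, then continues or ends).

(alphabet
 (name DNA)
 (token (a c g t))
 (complement (t g c a))
 (wildcard * n x))

(grammar
 (name jc69)
 (rate (u 1.0))

 (chain
  (terminal JC)
  (&foreach-token tok1
   (&foreach-token tok2
    (&if (&eq tok1 tok2)
     () ;; if tok1 == tok2, expand to an empty list (ignored by parser)
     (mutate (from (tok1)) (to (tok2)) (rate u))))))

 (transform (from (start)) (to (emit)) (prob 1))
 (transform (from (emit)) (to (JC emit*)))
 (transform (from (emit*)) (to (emit)))
 (transform (from (emit)) (to (emit)) (prob 1))
 (transform (from (emit)) (to ()) (prob 1)))
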