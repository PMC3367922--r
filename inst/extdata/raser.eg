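;; Latent-variable slow/fast chain: DNA tokens augmented with a hidden
;; class in {s, f}; substitutions within a class follow Jukes-Cantor scaled
;; by the class rate, and classes interconvert with rates r_sf / r_fs.
;; Five free parameters in total.  The class is surfaced through the
;; Stockholm #=GR row CLASS.

(alphabet
 (name DNA)
 (token (a c g t))
 (complement (t g c a))
 (wildcard * n x))

(grammar
 (name raser)
 (rate (s 0.1) (f 2.0) (r_sf 0.01) (r_fs 0.01) (u 1.0))

 (chain
  (hidden-class (row CLASS) (label (s f)))
  (terminal RASER)
  (&foreach class1 (s f)
   (&foreach class2 (s f)
    (&foreach-token tok1
     (&foreach-token tok2
      (&if (&eq class1 class2)
       (&if (&eq tok1 tok2)
        () ;; class1 == class2 && tok1 == tok2: empty list (ignored)
        ;; class1 == class2 && tok1 != tok2
        (mutate (from (tok1 class1)) (to (tok2 class2)) (rate u class1)))
       (&if (&eq tok1 tok2)
        ;; class1 != class2 && tok1 == tok2
        (mutate (from (tok1 class1)) (to (tok2 class2))
                (rate (&cat r_ class1 class2)))
        ())))))))  ;; class1 != class2 && tok1 != tok2: ignored

 (transform (from (start)) (to (emit)) (prob 1))
 (transform (from (emit)) (to (RASER emit*)))
 (transform (from (emit*)) (to (emit)))
 (transform (from (emit)) (to (emit)) (prob 1))
 (transform (from (emit)) (to ()) (prob 1))
 (annotate (nonterminal emit) (row STATE) (label e)))
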