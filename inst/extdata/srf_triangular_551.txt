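# triangular spectral response fixture, center 551 nm
536 0.000000
537 0.066667
538 0.133333
539 0.200000
540 0.266667
541 0.333333
542 0.400000
543 0.466667
544 0.533333
545 0.600000
546 0.666667
547 0.733333
548 0.800000
549 0.866667
550 0.933333
551 1.000000
552 0.933333
553 0.866667
554 0.800000
555 0.733333
556 0.666667
557 0.600000
558 0.533333
559 0.466667
560 0.400000
561 0.333333
562 0.266667
563 0.200000
564 0.133333
565 0.066667
566 0.000000
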