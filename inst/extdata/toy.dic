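%
1	posemo
2	negemo
3	social
4	cogproc
5	percept
6	focuspast
7	focuspresent
8	article
9	ipron
%
pleasure	1
joy	1
happ*	1
love	1	3
grief	2
sad*	2
fear	2
mate	3
friend*	3
compan*	3
talk*	3
think*	4
know*	4
because	4
reason*	4
see	5
hear*	5
feel*	5
was	6
were	6
did	6
is	7
are	7
now	7
the	8
a	8
an	8
it	9
this	9
that	9
those	9
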