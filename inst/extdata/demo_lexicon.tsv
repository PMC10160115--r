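token	valence
love	3.2
loved	2.9
lovely	2.8
great	3.1
good	1.9
wonderful	2.7
happy	2.7
joy	2.8
delight	2.9
delighted	3.0
excellent	3.2
amazing	2.8
awesome	3.1
beautiful	2.9
best	3.2
fantastic	2.6
glad	2.0
fun	2.3
nice	1.8
enjoy	2.2
enjoyed	2.3
laugh	2.6
smile	2.1
kind	1.6
brilliant	2.8
perfect	2.7
win	2.8
hope	1.9
sweet	2.0
friend	2.2
hate	-2.7
hated	-3.2
terrible	-2.1
awful	-2.0
bad	-2.5
horrible	-2.5
sad	-2.1
angry	-2.3
fear	-1.9
cry	-2.0
pain	-2.5
worst	-3.1
ugly	-2.3
disgusting	-2.4
lose	-1.4
lost	-1.3
kill	-3.0
dead	-3.3
war	-2.9
evil	-3.4
wrong	-2.1
fail	-2.3
hurt	-2.4
afraid	-2.0
alone	-1.0
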