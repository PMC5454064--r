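a
an
the
and
or
but
if
then
so
of
to
in
on
at
by
for
with
about
as
is
am
are
was
were
be
been
being
i
me
my
mine
we
our
you
your
he
him
his
she
her
it
its
they
them
their
this
that
these
those
there
here
what
which
who
how
when
where
why
do
does
did
doing
have
has
had
having
will
would
can
could
should
shall
may
might
must
just
very
really
quite
some
any
all
more
most
feeling
feel
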